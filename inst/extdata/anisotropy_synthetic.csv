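,0,10,20,30,40,50,60,70,80,90,100,110,120,130,140,150,160,170,180
0.5,0.7575,0.764812269729709,0.785867111271824,0.818125,0.857695158457885,0.899804841542115,0.939375,0.971632888728176,0.992687730270291,1,0.992687730270291,0.971632888728176,0.939375,0.899804841542115,0.857695158457885,0.818125,0.785867111271824,0.764812269729709,0.7575
1,0.765,0.772086117057656,0.79248977793352,0.82375,0.862096339124136,0.902903660875864,0.94125,0.97251022206648,0.992913882942344,1,0.992913882942344,0.97251022206648,0.94125,0.902903660875864,0.862096339124136,0.82375,0.79248977793352,0.772086117057656,0.765
2,0.78,0.78663381171355,0.805735111256912,0.835,0.870898700456638,0.909101299543362,0.945,0.974264888743088,0.99336618828645,1,0.99336618828645,0.974264888743088,0.945,0.909101299543362,0.870898700456638,0.835,0.805735111256912,0.78663381171355,0.78
3,0.795,0.801181506369444,0.818980444580305,0.84625,0.87970106178914,0.91529893821086,0.94875,0.976019555419695,0.993818493630556,1,0.993818493630556,0.976019555419695,0.94875,0.91529893821086,0.87970106178914,0.84625,0.818980444580305,0.801181506369444,0.795
5,0.825,0.830276895681233,0.845471111227089,0.86875,0.897305784454144,0.927694215545856,0.95625,0.979528888772911,0.994723104318767,1,0.994723104318767,0.979528888772911,0.95625,0.927694215545856,0.897305784454144,0.86875,0.845471111227089,0.830276895681233,0.825
8,0.87,0.873919979648916,0.885207111197266,0.9025,0.92371286845165,0.94628713154835,0.9675,0.984792888802734,0.996080020351084,1,0.996080020351084,0.984792888802734,0.9675,0.94628713154835,0.92371286845165,0.9025,0.885207111197266,0.873919979648916,0.87
12,0.93,0.932110758272493,0.938188444490836,0.9475,0.958922313781657,0.971077686218343,0.9825,0.991811555509164,0.997889241727507,1,0.997889241727507,0.991811555509164,0.9825,0.971077686218343,0.958922313781657,0.9475,0.938188444490836,0.932110758272493,0.93
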