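# Synthetic HDR source configuration (Ir-192-like magnitudes; the radial
# dose coefficients and the anisotropy table are synthetic stand-ins, not
# consensus data for any commercial source).
air_kerma_strength: 19700.0
dose_rate_constant: 1.109
capsule_length_cm: 0.36
radial_coeffs: [0.0, 0.0, 0.9930125, 0.01, -0.002, 0.0]
radial_decay: 0.0025
anisotropy_file: anisotropy_synthetic.csv
r0_cm: 2.0
theta0_deg: 90.0
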