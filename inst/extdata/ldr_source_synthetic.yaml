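# Synthetic LDR seed configuration (I-125-like magnitudes; point-source
# approximation, synthetic radial dose function).
air_kerma_strength: 0.38
dose_rate_constant: 0.965
capsule_length_cm: 0.0
radial_coeffs: [0.0, 0.0, 1.4190675, 0.0, 0.0, 0.0]
radial_decay: 0.35
anisotropy_file: point
r0_cm: 1.0
theta0_deg: 90.0
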