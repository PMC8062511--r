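plaque:
  very_soft:
    order: 2
    coefficients:
      C10: 0.0032
      C20: 0.048
    yield_strain: 0.34
  soft:
    order: 2
    coefficients:
      C10: 0.014
      C20: 0.21
    yield_strain: 0.34
  neutral:
    order: 2
    coefficients:
      C10: 0.04
      C20: 0.6
    yield_strain: 0.34
  stiff:
    order: 2
    coefficients:
      C10: 0.16
      C20: 2.4
    yield_strain: 0.34
  very_stiff:
    order: 2
    coefficients:
      C10: 0.64
      C20: 9.6
    yield_strain: 0.34
normal_wall:
  order: 6
  coefficients:
    C10: 0.02
    C20: 0.09
    C30: 0.35
    C40: 0.0
    C50: 0.0
    C60: 1.5
pt_cr:
  elastic_modulus: 203000.0
  yield_stress: 480.0
  hardening:
    plastic_strain:
    - 0.0
    - 0.05
    - 0.2
    - 0.4
    stress:
    - 480.0
    - 600.0
    - 850.0
    - 1000.0
balloon:
  elastic_modulus: 900.0
  thickness: 0.05
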