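# PC-SAFT pure-component parameters (2B association scheme) and binary
# interaction parameters for aqueous glycine and l-alanine.
# Units: molar_mass g/mol, sigma angstrom, u_k K, eps_assoc_k K.
components:
  - id: l-alanine
    molar_mass: 89.1
    m_seg: 5.4647
    sigma: 2.5222
    u_k: 287.59
    eps_assoc_k: 3176.60
    kappa_assoc: 0.0819
    n_sites: 2B
  - id: glycine
    molar_mass: 75.1
    m_seg: 4.8495
    sigma: 2.3270
    u_k: 216.96
    eps_assoc_k: 2598.06
    kappa_assoc: 0.0393
    n_sites: 2B
  - id: water
    molar_mass: 18.015
    m_seg: 1.2047
    sigma:
      type: temperature_exponential
      base: 2.7927
      a1: 10.11
      b1: -0.01775
      a2: -1.417
      b2: -0.01146
    u_k: 353.94
    eps_assoc_k: 2425.67
    kappa_assoc: 0.0451
    n_sites: 2B
binary_interactions:
  - pair: [l-alanine, water]
    kij_ref: -0.0612
    kij_slope: 2.91e-04
  - pair: [glycine, water]
    kij_ref: -0.0585
    kij_slope: 0.0
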