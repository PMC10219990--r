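# Illustrative T1D-style risk score model.  The structure mirrors the
# published GRS family (weighted effect-allele dosages, HLA diplotype
# interaction weights, proxy substitution, an imputation-quality floor,
# affine normalization); the weights here are EXAMPLE values for
# demonstrating and testing the engine, not a published weight table.
name: GRS_example
r2_min: 0.97
normalization: [0.0, 0.1]
snp_terms:
  - {id: rs2476601,  effect_allele: A, weight: 0.98}
  - {id: rs2187668,  effect_allele: T, weight: 1.27}
  - {id: rs689,      effect_allele: T, weight: 0.69}
  - {id: rs12722495, effect_allele: A, weight: 0.52}
  - {id: rs3184504,  effect_allele: T, weight: 0.29}
  - {id: rs1265564,  effect_allele: A, weight: 0.22}
  - {id: rs2292239,  effect_allele: T, weight: 0.30}
proxy_map:
  - {variant: rs2187668, proxy: rs9273369}
interaction_terms:
  - {hap1: DR3, hap2: DR4, weight: 3.87}
  - {hap1: DR3, hap2: DR3, weight: 3.11}
  - {hap1: DR4, hap2: DR4, weight: 3.26}
  - {hap1: DR4, hap2: X,   weight: 2.20}
  - {hap1: DR3, hap2: X,   weight: 1.80}
  - {hap1: DR15, weight: -2.29}
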