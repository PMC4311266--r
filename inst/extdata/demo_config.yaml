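# Demo: three synthetic family cohorts with a G6PC2-like rare-variant
# architecture; fasting-glucose-like quantitative trait.
seed: 42
trait: trait
trait_kind: quantitative
transform: none
covariates: [age, sex]
family_col: family_id
gene: GENE1
condition: [snv_common]
simulate:
  cohort_n: [2400, 2000, 1600]
  sibship_sizes: {"1": 0.6, "2": 0.25, "3": 0.15}
  family_sd: 0.3
  residual_sd: 0.8
  covariate_effects: {age: 0.005, sex: 0.1}
  # opposing-direction effects on three rare-allele haplotypes
  hap_effects: {H03: 0.5, H04: -0.45, H05: 0.45}
  drop: {cohort3: [H17]}
filters:
  mac_min: 20
  gene_maf_max: 0.01
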