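# Demo scenario: 200 cell lines over 4 tissues, three planted switches
# (one tissue-confounded), background unimodal analytes, 5% missingness.
n_cells: 200
tissues:
  breast: 60
  lung: 60
  skin: 40
  colon: 40
n_unimodal: 30
missing_rate: 0.05
tissue_effect_sd: 1
switches:
  - id: CDH1
    layers: [protein, mrna]
    pi_high: 0.5
    delta_mu: 4
    coupling_rho: 0.95
  - id: CLDN7
    layers: [protein, mrna]
    pi_high: 0.35
    delta_mu: 4
    coupling_rho: 0.9
  - id: LCK
    layers: [protein]
    pi_high: 0.2
    delta_mu: 5
    coupling_rho: 1.0
    tissue_bias:
      skin: 0.9
      breast: 0.01
      lung: 0.01
      colon: 0.01
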