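# Example two-class simulation scenario: 120 samples, 1,000 genes,
# a diffuse 20-gene signature at standardized fold change 1.0.
n: 120
p: 1000
m: 20
effect: 1.0
prevalence: 0.5
covariance: identity
seed: 42
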