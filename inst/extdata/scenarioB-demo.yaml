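# Small scenario-B demonstration grid: type I error of the correctly
# specified mixed model and the grouping-omitting pooled regression.
m_values: [2, 5, 8]
variances: [0.01]
effect: "null"
models: [M7, M10]
n_reps: 200
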