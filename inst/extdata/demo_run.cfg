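# painpheno run-all configuration (flat key: value format)
n_patients: 500
seed: 1
out: runs/demo
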