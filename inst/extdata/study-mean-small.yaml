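# Small Type I error study: equality-of-means model, 4 binary items.
kind: type1
family: mean
J: 4
N: [250]
replications: 200
seed: 20260920
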