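pattern	count
100	65
110	65
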