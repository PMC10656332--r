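pattern	count
000	20
001	15
010	10
011	15
101	15
110	25
111	30
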