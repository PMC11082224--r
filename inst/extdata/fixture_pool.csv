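"id","score","label"
1,0.1,0
2,0.2,0
3,0.3,1
4,0.4,0
5,0.6,1
6,0.7,0
7,0.8,1
8,0.9,1
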