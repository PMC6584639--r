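"k","count"
1,24
2,73
3,8
4,3
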