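label,dE
1*,-43.9
2*,-54.6
3*,-55.2
4*,-59.8
5*,-61.5
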