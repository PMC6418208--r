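element,a,b,c,d
a,0,0.697,0.214,0.786
b,0.697,0,0.580,0.692
c,0.214,0.580,0,0.804
d,0.786,0.692,0.804,0
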