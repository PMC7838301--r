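channel,minus2,minus1,plus1,plus2
126,0.0,0.0,6.1,0.3
127,0.0,0.5,6.7,0.2
128,0.0,1.1,4.2,0.3
129,0.0,1.7,4.1,0.2
130,0.1,1.6,3.2,0.1
131,0.2,3.2,2.8,0.0
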