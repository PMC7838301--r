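channel,minus2,minus1,plus1,plus2
126,0.0,0.0,6.1,0.3
127N,0.0,0.4,6.5,0.2
127C,0.0,0.6,6.7,0.2
128C,0.0,1.1,4.2,0.3
129N,0.0,1.4,4.4,0.2
130C,0.1,1.6,3.2,0.1
131,0.2,3.2,2.8,0.0
131C,0.2,3.4,2.6,0.0
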