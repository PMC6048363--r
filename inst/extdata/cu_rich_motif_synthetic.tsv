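base	p1	p2	p3	p4	p5
A	0.02	0.02	0.02	0.02	0.02
C	0.04	0.88	0.04	0.04	0.88
G	0.04	0.05	0.04	0.04	0.05
U	0.90	0.05	0.90	0.90	0.05
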