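code,label
11,C11
14,C14
20,C20
50,C50
70,C70
90,C90
100,C100
110,C110
120,C120
130,C130
150,C150
190,C190
210,C210
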