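group	kind	emboss	lehninger	bjellqvist
Nterm	basic	8.6	9.69	7.5
Cterm	acidic	3.6	2.34	3.55
K	basic	10.8	10.53	10.0
R	basic	12.5	12.48	12.0
H	basic	6.5	6.0	5.98
D	acidic	3.9	3.86	4.05
E	acidic	4.1	4.25	4.45
C	acidic	8.5	8.33	9.0
Y	acidic	10.1	10.07	10.0
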