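scheme_pos	human	llama
1	E	Q
5	V	Q
11	L	V
35	G,S	Y
37	V	F
44	G	E
45	L	R
47	W	F
50	A	S
74	K	A
78	L	V
83	R	K
89	V	L,T
91	Y	F
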