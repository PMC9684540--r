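res_a	res_b	dmin	dmax	orientation
L	I	4.5	7.5	packed
L	L	4.5	7.5	packed
I	I	4.5	7.5	packed
V	L	4.2	7.0	packed
V	I	4.2	7.0	packed
V	V	4.0	6.5	packed
A	L	4.0	6.5	packed
A	I	4.0	6.5	packed
A	V	3.8	6.0	packed
A	A	3.6	5.5	packed
F	L	4.8	8.0	packed
F	I	4.8	8.0	packed
F	V	4.5	7.5	packed
F	F	5.0	8.5	stacked
F	M	4.8	8.0	packed
M	L	4.6	7.8	packed
M	I	4.6	7.8	packed
M	M	4.6	7.8	packed
W	L	5.0	8.5	packed
W	I	5.0	8.5	packed
W	V	4.8	8.0	packed
W	F	5.2	9.0	stacked
Y	L	4.8	8.2	packed
Y	I	4.8	8.2	packed
Y	F	5.0	8.5	stacked
Y	V	4.6	7.8	packed
L	V	4.2	7.0	packed
I	A	4.0	6.5	packed
M	F	4.8	8.0	packed
M	V	4.4	7.2	packed
W	M	5.0	8.5	packed
Y	M	4.8	8.2	packed
F	A	4.4	7.2	packed
W	A	4.8	7.8	packed
Y	A	4.5	7.5	packed
L	F	4.8	8.0	packed
E	K	5.5	9.0	salt_bridge
D	R	5.0	8.5	salt_bridge
E	R	5.5	9.0	salt_bridge
D	K	5.0	8.5	salt_bridge
N	Q	4.8	8.0	polar
S	T	4.0	7.0	polar
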