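residue	n_human	n_vertebrate
G	1080	171377
S	862	131638
A	505	80871
T	92	20011
L	91	18102
V	83	17729
F	80	13377
Y	74	14295
N	65	18225
D	53	11274
M	50	8552
E	46	9115
K	41	7301
I	40	7507
C	36	6986
H	31	6596
P	28	9298
Q	22	3929
R	22	6320
W	12	2754
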