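id	type	community
g1	G	1
g2	G	1
g3	G	1
g4	G	2
g5	G	1
g6	G	2
g7	G	2
g8	G	1
g9	G	2
g10	G	1
g11	G	1
g12	G	2
g13	G	1
g14	G	1
g15	G	1
g16	G	2
g17	G	2
g18	G	2
g19	G	1
g20	G	2
g21	G	2
g22	G	1
g23	G	1
g24	G	1
g25	G	1
g26	G	2
g27	G	2
g28	G	2
g29	G	1
g30	G	2
g31	G	2
g32	G	2
g33	G	1
g34	G	2
g35	G	2
g36	G	2
g37	G	1
g38	G	1
g39	G	1
g40	G	2
d1	D	1
d2	D	1
d3	D	1
d4	D	2
d5	D	1
d6	D	1
d7	D	1
d8	D	2
d9	D	2
d10	D	2
d11	D	2
d12	D	2
d13	D	1
d14	D	1
d15	D	2
d16	D	1
d17	D	1
d18	D	2
d19	D	2
d20	D	2
o1	O	2
o2	O	1
o3	O	2
o4	O	2
o5	O	1
o6	O	1
o7	O	2
o8	O	2
o9	O	2
o10	O	1
o11	O	1
o12	O	2
o13	O	1
o14	O	2
o15	O	1
o16	O	1
o17	O	2
o18	O	2
o19	O	1
o20	O	1
o21	O	2
o22	O	2
o23	O	1
o24	O	2
o25	O	2
o26	O	1
o27	O	1
o28	O	1
o29	O	1
o30	O	2
s1	S	2
s2	S	2
s3	S	1
s4	S	1
s5	S	2
s6	S	1
s7	S	2
s8	S	1
s9	S	1
s10	S	2
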