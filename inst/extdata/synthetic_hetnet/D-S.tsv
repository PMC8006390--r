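src	dst	weight
d2	s1	1
d11	s1	1
d12	s1	1
d8	s2	1
d18	s2	1
d19	s2	1
d3	s3	1
d17	s3	1
d5	s4	1
d4	s5	1
d19	s5	1
d6	s6	1
d7	s6	1
d15	s7	1
d20	s7	1
d2	s9	1
d7	s9	1
d16	s9	1
d17	s9	1
d4	s10	1
d9	s10	1
d15	s10	1
d19	s10	1
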