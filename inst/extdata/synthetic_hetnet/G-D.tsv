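src	dst	weight
g2	d1	1
g10	d1	1
g13	d1	1
g14	d1	1
g33	d1	1
g38	d1	1
g2	d2	1
g3	d2	1
g5	d2	1
g8	d2	1
g10	d2	1
g13	d2	1
g22	d2	1
g29	d2	1
g33	d2	1
g37	d2	1
g39	d2	1
g3	d3	1
g8	d3	1
g15	d3	1
g19	d3	1
g20	d3	1
g22	d3	1
g24	d3	1
g29	d3	1
g33	d3	1
g36	d3	1
g40	d3	1
g6	d4	1
g12	d4	1
g16	d4	1
g17	d4	1
g26	d4	1
g30	d4	1
g31	d4	1
g34	d4	1
g35	d4	1
g2	d5	1
g8	d5	1
g13	d5	1
g14	d5	1
g22	d5	1
g23	d5	1
g30	d5	1
g37	d5	1
g38	d5	1
g11	d6	1
g19	d6	1
g23	d6	1
g25	d6	1
g29	d6	1
g3	d7	1
g8	d7	1
g19	d7	1
g29	d7	1
g38	d7	1
g39	d7	1
g34	d8	1
g35	d8	1
g36	d8	1
g6	d9	1
g9	d9	1
g12	d9	1
g16	d9	1
g20	d9	1
g26	d9	1
g31	d9	1
g34	d9	1
g35	d9	1
g40	d9	1
g4	d10	1
g17	d10	1
g28	d10	1
g34	d10	1
g36	d10	1
g9	d11	1
g27	d11	1
g31	d11	1
g34	d11	1
g35	d11	1
g6	d12	1
g30	d12	1
g31	d12	1
g40	d12	1
g1	d13	1
g5	d13	1
g11	d13	1
g14	d13	1
g23	d13	1
g24	d13	1
g25	d13	1
g29	d13	1
g32	d13	1
g37	d13	1
g3	d14	1
g10	d14	1
g13	d14	1
g14	d14	1
g22	d14	1
g29	d14	1
g33	d14	1
g6	d15	1
g7	d15	1
g9	d15	1
g12	d15	1
g18	d15	1
g20	d15	1
g21	d15	1
g30	d15	1
g34	d15	1
g2	d16	1
g14	d16	1
g15	d16	1
g22	d16	1
g23	d16	1
g24	d16	1
g1	d17	1
g3	d17	1
g14	d17	1
g15	d17	1
g23	d17	1
g29	d17	1
g37	d17	1
g38	d17	1
g9	d18	1
g12	d18	1
g20	d18	1
g26	d18	1
g28	d18	1
g32	d18	1
g38	d18	1
g40	d18	1
g6	d19	1
g12	d19	1
g18	d19	1
g21	d19	1
g26	d19	1
g29	d19	1
g31	d19	1
g35	d19	1
g4	d20	1
g7	d20	1
g8	d20	1
g12	d20	1
g17	d20	1
g28	d20	1
g36	d20	1
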