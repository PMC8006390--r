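src	dst	weight
g2	g3	1
g1	g5	1
g2	g5	1
g3	g5	1
g1	g8	1
g5	g8	1
g4	g9	1
g1	g10	1
g10	g2	1
g11	g5	1
g11	g8	1
g10	g11	1
g12	g4	1
g12	g9	1
g1	g13	1
g15	g2	1
g15	g3	1
g16	g4	1
g16	g17	1
g17	g18	1
g1	g19	1
g10	g19	1
g15	g19	1
g20	g6	1
g20	g7	1
g18	g21	1
g20	g21	1
g1	g22	1
g22	g5	1
g22	g8	1
g11	g22	1
g14	g22	1
g15	g22	1
g1	g23	1
g23	g5	1
g11	g23	1
g14	g23	1
g16	g23	1
g1	g24	1
g11	g24	1
g23	g24	1
g25	g8	1
g15	g25	1
g19	g25	1
g21	g26	1
g27	g6	1
g27	g7	1
g12	g27	1
g18	g27	1
g21	g27	1
g28	g4	1
g28	g6	1
g16	g28	1
g29	g5	1
g19	g29	1
g22	g29	1
g24	g29	1
g25	g29	1
g30	g4	1
g17	g30	1
g28	g30	1
g31	g4	1
g31	g7	1
g31	g9	1
g12	g31	1
g16	g31	1
g32	g7	1
g32	g9	1
g20	g32	1
g27	g32	1
g28	g32	1
g3	g33	1
g13	g33	1
g22	g33	1
g23	g33	1
g31	g34	1
g35	g6	1
g16	g35	1
g17	g35	1
g30	g35	1
g32	g35	1
g33	g35	1
g34	g35	1
g36	g7	1
g12	g36	1
g17	g36	1
g30	g36	1
g2	g37	1
g13	g37	1
g14	g37	1
g19	g37	1
g25	g37	1
g33	g37	1
g1	g38	1
g3	g38	1
g13	g38	1
g14	g38	1
g22	g38	1
g23	g38	1
g24	g38	1
g25	g38	1
g29	g38	1
g39	g8	1
g13	g39	1
g22	g39	1
g38	g39	1
g40	g9	1
g12	g40	1
g26	g40	1
g27	g40	1
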