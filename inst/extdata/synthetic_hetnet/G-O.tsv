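src	dst	weight
g7	o1	1
g17	o1	1
g27	o1	1
g30	o1	1
g4	o3	1
g12	o3	1
g28	o3	1
g30	o3	1
g31	o3	1
g34	o3	1
g36	o3	1
g11	o4	1
g18	o4	1
g20	o4	1
g30	o4	1
g1	o5	1
g10	o5	1
g15	o5	1
g24	o5	1
g29	o5	1
g34	o5	1
g1	o6	1
g2	o6	1
g3	o6	1
g5	o6	1
g10	o6	1
g14	o6	1
g15	o6	1
g22	o6	1
g23	o6	1
g24	o6	1
g33	o6	1
g37	o6	1
g39	o6	1
g16	o7	1
g17	o7	1
g27	o7	1
g28	o7	1
g34	o7	1
g35	o7	1
g12	o8	1
g16	o8	1
g17	o8	1
g21	o8	1
g36	o8	1
g38	o8	1
g40	o8	1
g5	o9	1
g6	o9	1
g7	o9	1
g16	o9	1
g18	o9	1
g31	o9	1
g36	o9	1
g5	o10	1
g10	o10	1
g14	o10	1
g1	o11	1
g2	o11	1
g23	o11	1
g25	o11	1
g29	o11	1
g37	o11	1
g38	o11	1
g17	o12	1
g19	o12	1
g20	o12	1
g31	o12	1
g32	o12	1
g13	o13	1
g14	o13	1
g15	o13	1
g33	o13	1
g37	o13	1
g39	o13	1
g6	o14	1
g8	o14	1
g9	o14	1
g18	o14	1
g27	o14	1
g30	o14	1
g40	o14	1
g11	o15	1
g24	o15	1
g33	o15	1
g10	o16	1
g19	o16	1
g23	o16	1
g25	o16	1
g6	o17	1
g9	o17	1
g16	o17	1
g17	o17	1
g20	o17	1
g27	o17	1
g28	o17	1
g31	o17	1
g32	o17	1
g36	o17	1
g7	o18	1
g16	o18	1
g20	o18	1
g21	o18	1
g30	o18	1
g32	o18	1
g1	o19	1
g37	o19	1
g39	o19	1
g1	o20	1
g3	o20	1
g10	o20	1
g23	o20	1
g25	o20	1
g29	o20	1
g37	o20	1
g38	o20	1
g39	o20	1
g6	o21	1
g10	o21	1
g20	o21	1
g21	o21	1
g36	o21	1
g4	o22	1
g7	o22	1
g9	o22	1
g12	o22	1
g16	o22	1
g17	o22	1
g18	o22	1
g20	o22	1
g21	o22	1
g26	o22	1
g27	o22	1
g28	o22	1
g35	o22	1
g40	o22	1
g1	o23	1
g6	o23	1
g13	o23	1
g19	o23	1
g22	o23	1
g23	o23	1
g24	o23	1
g37	o23	1
g12	o24	1
g16	o24	1
g18	o24	1
g34	o24	1
g36	o24	1
g40	o24	1
g4	o25	1
g16	o25	1
g18	o25	1
g21	o25	1
g27	o25	1
g32	o25	1
g2	o26	1
g8	o26	1
g10	o26	1
g11	o26	1
g13	o26	1
g23	o26	1
g39	o26	1
g5	o27	1
g10	o27	1
g24	o27	1
g39	o27	1
g2	o28	1
g14	o28	1
g18	o28	1
g19	o28	1
g33	o28	1
g38	o28	1
g1	o29	1
g5	o29	1
g24	o29	1
g37	o29	1
g6	o30	1
g7	o30	1
g13	o30	1
g20	o30	1
g32	o30	1
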