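0	mr_hi
1	mr_hi
2	mr_hi
3	mr_hi
4	mr_hi
5	mr_hi
6	mr_hi
7	mr_hi
8	officer
9	officer
10	mr_hi
11	mr_hi
12	mr_hi
13	mr_hi
14	officer
15	officer
16	mr_hi
17	mr_hi
18	officer
19	mr_hi
20	officer
21	mr_hi
22	officer
23	officer
24	officer
25	officer
26	officer
27	officer
28	officer
29	officer
30	officer
31	officer
32	officer
33	officer
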