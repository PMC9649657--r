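resi	angle	target_deg	tolerance_deg
1	psi	-45	20
2	phi	-60	20
2	psi	-45	20
3	phi	-60	20
3	psi	-45	20
4	phi	-60	20
4	psi	-45	20
5	phi	-60	20
5	psi	-45	20
6	phi	-60	20
6	psi	-45	20
7	phi	-60	20
7	psi	-45	20
8	phi	-60	20
8	psi	-45	20
9	phi	-60	20
9	psi	-45	20
10	phi	-60	20
10	psi	-44.9999999999999	20
11	phi	-60	20
11	psi	-45	20
12	phi	-60	20
12	psi	-45	20
13	phi	-60	20
13	psi	-45	20
14	phi	-120	20
14	psi	120	20
15	phi	-120	20
15	psi	120	20
16	phi	59.9999999999999	20
16	psi	45	20
17	phi	-140	20
17	psi	160	20
18	phi	-60	20
18	psi	-44.9999999999999	20
19	phi	-60	20
19	psi	-45	20
20	phi	-60	20
20	psi	-45	20
21	phi	-60	20
21	psi	-45	20
22	phi	-60	20
22	psi	-45	20
23	phi	-60	20
23	psi	-45	20
24	phi	-60	20
24	psi	-45	20
25	phi	-60	20
25	psi	-45	20
26	phi	-60	20
26	psi	-45	20
27	phi	-60	20
27	psi	-45	20
28	phi	-60	20
28	psi	-45	20
29	phi	-60	20
29	psi	-45	20
30	phi	-60	20
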