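id	size	n_edges	redundancy	edges	orbits
0	2	1	0	0-1	0,0
1	3	2	0	0-1,0-2	2,1,1
2	3	3	1	0-1,0-2,1-2	3,3,3
3	4	3	0	0-1,0-3,1-2	5,5,4,4
4	4	3	0	0-1,0-2,0-3	7,6,6,6
5	4	4	1	0-2,0-3,1-2,1-3	8,8,8,8
6	4	4	1	0-1,0-2,0-3,1-2	11,10,10,9
7	4	5	2	0-1,0-2,0-3,1-2,1-3	13,13,12,12
8	4	6	3	0-1,0-2,0-3,1-2,1-3,2-3	14,14,14,14
9	5	4	0	0-2,0-4,1-2,1-3	16,16,17,15,15
10	5	4	0	0-1,0-3,0-4,1-2	21,20,18,19,19
11	5	4	0	0-1,0-2,0-3,0-4	23,22,22,22,22
12	5	5	1	0-3,0-4,1-2,1-4,2-3	24,24,24,24,24
13	5	5	1	0-2,0-3,0-4,1-2,1-3	28,26,27,27,25
14	5	5	1	0-1,0-4,1-2,1-3,2-3	30,32,31,31,29
15	5	5	1	0-1,0-2,0-4,1-2,1-3	35,35,34,33,33
16	5	5	1	0-1,0-2,0-3,0-4,1-2	38,37,37,36,36
17	5	6	2	0-2,0-3,0-4,1-2,1-3,1-4	40,40,39,39,39
18	5	6	2	0-1,0-3,0-4,1-2,1-4,2-3	43,43,41,41,42
19	5	6	2	0-1,0-2,0-4,1-2,1-3,2-3	46,47,47,45,44
20	5	6	2	0-1,0-2,0-3,0-4,1-4,2-3	49,48,48,48,48
21	5	6	2	0-1,0-2,0-3,0-4,1-2,1-3	53,52,51,51,50
22	5	7	3	0-2,0-3,0-4,1-2,1-3,1-4,2-3	55,55,56,56,54
23	5	7	3	0-1,0-2,0-3,0-4,1-2,1-4,2-3	59,58,58,57,57
24	5	7	3	0-1,0-2,0-3,0-4,1-2,1-3,2-3	62,61,61,61,60
25	5	7	3	0-1,0-2,0-3,0-4,1-2,1-3,1-4	64,64,63,63,63
26	5	8	4	0-1,0-2,0-3,0-4,1-3,1-4,2-3,2-4	66,65,65,65,65
27	5	8	4	0-1,0-2,0-3,0-4,1-2,1-3,1-4,2-3	69,69,68,68,67
28	5	9	5	0-1,0-2,0-3,0-4,1-2,1-3,1-4,2-3,2-4	71,71,71,70,70
29	5	10	6	0-1,0-2,0-3,0-4,1-2,1-3,1-4,2-3,2-4,3-4	72,72,72,72,72
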