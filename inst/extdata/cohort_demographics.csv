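patient_id,nihss,onset_time_h
1,6,24
2,5,72
3,5,48
4,11,48
5,10,19
6,10,48
7,2,24
8,3,48
9,1,24
10,2,10
11,5,20
12,2,6
13,3,12
14,10,24
15,9,9
16,11,20
17,1,72
18,14,48
19,13,72
20,14,24
21,6,24
22,7,72
23,6,72
24,5,10
25,8,24
26,7,17
27,4,24
28,3,72
29,1,48
30,12,24
31,2,144
32,3,96
33,8,96
34,1,144
35,10,144
36,2,96
37,5,144
38,10,120
39,3,96
40,5,168
41,8,96
42,2,96
43,1,96
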