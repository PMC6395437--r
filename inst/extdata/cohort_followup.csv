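patient_id,followup_day
1,6
1,34
2,4
3,4
4,6
5,6
6,4
7,2
7,7
8,3
8,8
8,38
9,2
9,7
10,2
11,2
11,8
12,2
12,8
13,2
13,8
21,2
21,12
21,32
22,10
22,32
24,2
24,8
24,39
25,2
25,8
26,3
27,2
28,4
29,3
31,7
31,12
31,45
32,7
32,8
32,31
33,7
37,11
43,11
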