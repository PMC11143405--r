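waiting_time_s
83
51
87
60
28
95
8
27
15
10
18
16
29
54
91
8
17
55
10
35
47
77
36
17
21
36
18
40
10
7
34
27
28
56
8
25
68
146
89
18
73
69
9
37
10
82
29
8
60
61
61
18
169
25
8
26
11
83
11
42
17
14
9
12
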