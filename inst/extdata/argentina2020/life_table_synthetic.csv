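age,residual_le
0,76.0
5,71.5
10,66.6
15,61.7
20,56.9
25,52.1
30,47.4
35,42.6
40,37.9
45,33.3
50,28.8
55,24.5
60,20.4
65,16.5
70,13.0
75,9.9
80,7.3
85,5.2
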