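patient_no,phase,monitoring_hours,n_postures
1,pre,14.5,17
2,pre,16,1
5,pre,9.3,3
6,pre,9.5,3
7,pre,15,7
8,pre,20.4,6
9,pre,23.4,9
10,pre,9,5
11,pre,51,31
12,pre,45,5
13,pre,34.5,5
15,pre,19,5
16,pre,45.3,37
17,pre,22,6
18,pre,35,9
19,pre,13.5,6
22,pre,14.5,15
1,post,3,2
2,post,14.5,1
5,post,23,8
6,post,9,4
7,post,15.8,2
8,post,22,12
9,post,22.5,22
10,post,25,10
11,post,23,1
12,post,27.5,15
13,post,24,14
15,post,22.5,2
16,post,40.8,8
17,post,34.5,13
18,post,11.7,1
19,post,17.3,11
22,post,15.3,5
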