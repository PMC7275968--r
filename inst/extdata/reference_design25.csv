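mix,AT,PR,HZ,LV,validation
1,15,5.5,5.5,4,FALSE
2,15,1,1,7,FALSE
3,5,1,10,2.5,TRUE
4,5,10,3.5,7,TRUE
5,25,3.5,10,4,FALSE
6,10,10,5.5,2.5,FALSE
7,25,5.5,3.5,2.5,FALSE
8,15,3.5,3.5,5.5,FALSE
9,10,3.5,8,7,TRUE
10,10,8,10,5.5,FALSE
11,20,10,8,4,FALSE
12,25,8,5.5,7,FALSE
13,20,5.5,10,7,FALSE
14,15,10,10,1,FALSE
15,25,10,1,5.5,TRUE
16,25,1,8,1,FALSE
17,5,8,1,4,FALSE
18,20,1,5.5,5.5,TRUE
19,5,5.5,8,5.5,FALSE
20,15,8,8,2.5,TRUE
21,20,8,3.5,1,FALSE
22,20,3.5,1,2.5,FALSE
23,10,1,3.5,4,TRUE
24,5,3.5,5.5,1,FALSE
25,10,5.5,1,1,FALSE
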