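id,sex,age_years,affected_side,akinesia_score,state,ledd_mg,duration_years
1,F,68,Right,8,On,625,5
2,F,76,Right,5,On,0,1
3,M,73,Left,13,On,0,4
4,M,54,Left,5,On,340,3
5,F,72,Left,4,On,37.5,30
6,F,69,Left,7,On,175,4
7,M,75,Left,17,On,400,8
8,M,69,Left,12,Off,1406,15
9,F,70,Left,9,On,891.5,10
10,F,52,Left,1,On,715,11
11,F,72,Left,15,On,100,1
12,M,69,Left,12,On,110,4
13,M,54,Right,14,Off,1344.5,11
14,F,68,Right,7,On,100,4
15,M,63,Left,19,On,1037.5,7
16,F,55,Right,20,Off,560,6
17,M,64,Left,12,On,0,3
18,F,69,Left,8,On,200,5
19,F,72,Left,14,On,975,18
20,M,52,Left,13,On,549,4
21,M,53,Right,11,On,1081,18
22,M,66,Left,14,On,752.2,8
23,F,66,Left,21,Off,948,5
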