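"alpha_deg","delta_deg"
0,180
1,179.97258512815
2,179.890348863437
3,179.753316255823
4,179.561529046768
5,179.315045656514
6,179.013941166289
7,178.658307295438
8,178.248252373483
9,177.783901307125
10,177.265395542197
11,176.69289302058
12,176.066568132085
13,175.386611661342
14,174.653230729679
15,173.866648732032
16,173.027105268897
17,172.134856073346
18,171.190172933128
19,170.193343607877
20,169.144671741464
21,168.044476769496
22,166.893093822022
23,165.690873621439
24,164.438182375668
25,163.135401666597
26,161.78292833385
27,160.381174353906
28,158.930566714607
29,157.431547285091
30,155.884572681199
31,154.29011412638
32,152.648657308157
33,150.960702230176
34,149.226763059907
35,147.447367972019
36,145.623058987491
37,143.754391808513
38,141.84193564921
39,139.886273062255
40,137.887999761416
41,135.847724440099
42,133.766068585931
43,131.643666291451
44,129.481164060957
45,127.279220613579
46,125.03850668262
47,122.75970481125
48,120.443509144594
49,118.090625218291
50,115.701769743577
51,113.277670388971
52,110.819065558618
53,108.326704167369
54,105.801345412645
55,103.243758543188
56,100.654722624734
57,98.0350263027049
58,95.3854675619769
59,92.7068534838098
60,90
61,87.2657316443407
62,84.5048813014604
63,81.7182899531184
64,78.9068064220339
65,76.0712871133259
66,73.212595753644
67,70.3316031280693
68,67.4291868148642
69,64.5062309181541
70,61.5636257986204
71,58.6022678022882
72,55.6230589874905
73,52.6269068500926
74,49.6147240470599
75,46.5874281184537
76,43.5459412079402
77,40.4911897818957
78,37.4241043471967
79,34.3456191677781
80,31.2566719800475
81,28.1582037072416
82,25.0511581728118
83,21.9364818129265
84,18.8151233881776
85,15.6880336945785
86,12.5561652739426
87,9.42047212372991
88,6.28190940645019
89,3.14143315871101
90,1.10218211923262e-14
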