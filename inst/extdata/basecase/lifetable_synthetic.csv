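"age","qx"
0,0.004
1,0.000232962625646205
2,0.000236249576602399
3,0.000239864088852126
4,0.000243838804168228
5,0.000248209616819484
6,0.000253015997595307
7,0.000258301350100631
8,0.000264113402527855
9,0.000270504638438362
10,0.000277532770433075
11,0.000285261260976721
12,0.000293759895065748
13,0.000303105409891868
14,0.000313382187168143
15,0.000324683014340743
16,0.000337109921531353
17,0.00035077510172743
18,0.000365801922484921
19,0.000382326038221859
20,0.000400496613080503
21,0.000420477665315055
22,0.000442449545247969
23,0.000466610560017622
24,0.000493178759642054
25,0.000522393900350471
26,0.000554519602694037
27,0.00058984572366505
28,0.000628690963926704
29,0.000671405733317254
30,0.000718375300038931
31,0.000770023251410845
32,0.00082681529675821
33,0.000889263445959743
34,0.000957930600391732
35,0.00103343559652924
36,0.0011164587462954
37,0.00120774792243394
38,0.00130812524173685
39,0.0014184944039094
40,0.00153984874924373
41,0.00167328010411116
42,0.00181998848961717
43,0.00198129277561188
44,0.00215864236964081
45,0.00235363003838862
46,0.00256800596772955
47,0.00280369317666973
48,0.00306280441026496
49,0.00334766064702396
50,0.00366081136734664
51,0.00400505674118745
52,0.00438347190531729
53,0.00479943351322254
54,0.00525664875373011
55,0.00575918704772305
56,0.00631151464565105
57,0.00691853236166184
58,0.00758561669278535
59,0.00831866458325259
60,0.00912414210421009
61,0.0100091373271303
62,0.010981417674285
63,0.0120494920307256
64,0.0132226778980362
65,0.0145111738591528
66,0.0159261376039009
67,0.0174797697343273
68,0.0191854035246632
69,0.0210576007495833
70,0.0231122536124339
71,0.0253666926976779
72,0.0278398007335179
73,0.0305521317751629
74,0.0335260351991137
75,0.0367857836256632
76,0.0403577035508156
77,0.0442703070590751
78,0.0485544224927935
79,0.0532433213585941
80,0.05837283804238
81,0.0639814780664953
82,0.070110509640528
83,0.0768040321165192
84,0.0841090136474241
85,0.0920752888556349
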