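age,q_all,cvd_fatality
0,1.9999800001335721e-05,0.10000000000000001
1,2.2103174082799271e-05,0.10000000000000001
2,2.4427756800671219e-05,0.10000000000000001
3,2.699681173101709e-05,0.10000000000000001
4,2.9836048849096741e-05,0.10000000000000001
5,3.2973881763598278e-05,0.10000000000000001
6,3.6441711992463155e-05,0.10000000000000001
7,4.0274243120252962e-05,0.10000000000000001
8,4.450982797810088e-05,0.10000000000000001
9,4.9190852313474309e-05,0.10000000000000001
10,5.436415878479206e-05,0.10000000000000001
11,6.0081515512400152e-05,0.10000000000000001
12,6.6400133868271816e-05,0.10000000000000001
13,7.338324067063251e-05,0.10000000000000001
14,8.1100710496495587e-05,0.10000000000000001
15,8.9629764419396629e-05,0.10000000000000001
16,9.9055742143860925e-05,0.10000000000000001
17,0.0001094729552332252,0.10000000000000001
18,0.00012098562993656525,0.10000000000000001
19,0.0001337089490072163,0.10000000000000001
20,0.00014777020288647691,0.10000000000000001
21,0.00016331006171121931,0.10000000000000001
22,0.00018048398079506534,0.10000000000000001
23,0.00019946375355617274,0.10000000000000001
24,0.00022043922731518339,0.10000000000000001
25,0.00024362019899282217,0.10000000000000001
26,0.00026923850950555384,0.10000000000000001
27,0.00029755035760647974,0.10000000000000001
28,0.00032883885606938001,0.10000000000000001
29,0.00036341685548002545,0.10000000000000001
30,0.00040163006350812935,0.10000000000000001
31,0.00044386049040301412,0.10000000000000001
32,0.0004905302546185375,0.10000000000000001
33,0.0005421057859454903,0.10000000000000001
34,0.00059910246735517259,0.10000000000000001
35,0.00066208976095483152,0.10000000000000001
36,0.00073169686806984213,0.10000000000000001
37,0.00080861897852568809,0.10000000000000001
38,0.00089362416975602432,0.10000000000000001
39,0.00098756102243768851,0.10000000000000001
40,0.0010913670260126462,0.10000000000000001
41,0.0012060778547253737,0.10000000000000001
42,0.0013328376027486044,0.10000000000000001
43,0.0014729100756265545,0.10000000000000001
44,0.0016276912446913094,0.10000000000000001
45,0.0017987229813425376,0.10000000000000001
46,0.0019877081991863665,0.10000000000000001
47,0.0021965275440336551,0.10000000000000001
48,0.0024272577847086474,0.10000000000000001
49,0.0026821920715430769,0.10000000000000001
50,0.0029638622443498575,0.10000000000000001
51,0.003275063387576993,0.10000000000000001
52,0.003618880847225725,0.10000000000000001
53,0.0039987199419265762,0.10000000000000001
54,0.0044183386192102603,0.10000000000000001
55,0.0048818833273578388,0.10000000000000001
56,0.0053939283930780624,0.10000000000000001
57,0.0059595192153452103,0.10000000000000001
58,0.0065842196057003255,0.10000000000000001
59,0.0072741636246508312,0.10000000000000001
60,0.0080361122818868314,0.10000000000000001
61,0.0088775154840269321,0.10000000000000001
62,0.0098065796264735772,0.10000000000000001
63,0.010832341234373044,0.10000000000000001
64,0.011964747059977188,0.10000000000000001
65,0.01321474103784015,0.10000000000000001
66,0.014594358482692638,0.10000000000000001
67,0.016116827884400053,0.10000000000000001
68,0.017796680606289472,0.10000000000000001
69,0.01964986872268959,0.10000000000000001
70,0.021693891133141352,0.10000000000000001
71,0.02394792795767009,0.10000000000000001
72,0.026432983041718816,0.10000000000000001
73,0.029172034171279781,0.10000000000000001
74,0.032190190307224698,0.10000000000000001
75,0.0355148547797004,0.10000000000000001
76,0.03917589292361312,0.10000000000000001
77,0.04320580206733704,0.10000000000000001
78,0.047639881089327263,0.10000000000000001
79,0.052516395909612101,0.10000000000000001
80,0.057876736261601613,0.10000000000000001
81,0.06376555786932403,0.10000000000000001
82,0.070230902710690102,0.10000000000000001
83,0.077324288354228221,0.10000000000000001
84,0.085100755393597405,0.10000000000000001
85,0.09361885975590567,0.10000000000000001
86,0.10294059412175671,0.10000000000000001
87,0.11313121987857488,0.10000000000000001
88,0.12425898796968271,0.10000000000000001
89,0.13639472376927841,0.10000000000000001
90,0.14961124782379598,0.10000000000000001
91,0.163982601130921,0.10000000000000001
92,0.17958304083666343,0.10000000000000001
93,0.19648577017724067,0.10000000000000001
94,0.21476136565840909,0.10000000000000001
95,0.23447586547817012,0.10000000000000001
96,0.25568848685174816,0.10000000000000001
97,0.27844894715695157,0.10000000000000001
98,0.30279437581850821,0.10000000000000001
99,0.32874582186221779,0.10000000000000001
100,0.35630438742658943,0.10000000000000001
101,0.38544705148466962,0.10000000000000001
102,0.4161222915879873,0.10000000000000001
103,0.44824566500048801,0.10000000000000001
104,0.48169557354484738,0.10000000000000001
105,0.51630950670683506,0.10000000000000001
106,0.5518811307513769,0.10000000000000001
107,0.58815866070714962,0.10000000000000001
108,0.6248450066216924,0.10000000000000001
109,0.66160021139296787,0.10000000000000001
110,1,0.10000000000000001
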