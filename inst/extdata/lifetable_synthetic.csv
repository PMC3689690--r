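age,qx_male,qx_female
0,6.11027165910993e-05,4.88824719635517e-05
1,6.68568287971461e-05,5.3485820634136e-05
2,7.31527924624498e-05,5.85226620889445e-05
3,8.00416285786643e-05,6.40338154124231e-05
4,8.75791615276844e-05,7.00639428523608e-05
5,9.58264711456991e-05,7.66619115617484e-05
6,0.000104850387304678,8.38811893688618e-05
7,0.000114724030999991,9.17802777765653e-05
8,0.000125527406313664,0.000100423185684595
9,0.000137348048026231,0.000109879947662761
10,0.000150281730099677,0.000120227190956279
11,0.000164433240739781,0.00013154875579735
12,0.000179917230280213,0.00014393637402732
13,0.000196859138714367,0.000157490411497263
14,0.000215396210333951,0.000172320680229099
15,0.000235678603630385,0.000188547326875677
16,0.000257870605375077,0.000206301804628772
17,0.000282151958617471,0.000225727936391085
18,0.000308719315251005,0.000246983077751839
19,0.000337787824777891,0.000270239389105087
20,0.000369592871981683,0.000295685227112541
21,0.000404391977392393,0.000323526666660245
22,0.00044246687570515,0.000353989165491675
23,0.000484125788710932,0.000387319384823059
24,0.000529705910816358,0.000423787180478752
25,0.000579576126885195,0.000463687780419053
26,0.000634139983935356,0.000507344165992962
27,0.000693838940185043,0.000555109675838827
28,0.000759155917073873,0.000607370853081934
29,0.000830619182200509,0.000664550558365007
30,0.000908806593633127,0.000727111373292066
31,0.000994350238777586,0.000795559321091766
32,0.00108794150394953,0.000870447933728147
33,0.00119033661399881,0.000952382697305687
34,0.00130236268480366,0.00104202591046665
35,0.00142492433519825,0.00114010199356185
36,0.00155901090894484,0.0012474032897154
37,0.00170570436171691,0.00136479640251619
38,0.00186618787275283,0.00149322911896743
39,0.00204175524587236,0.0016337379705339
40,0.00223382116994908,0.00178745648965317
41,0.00244393241469776,0.00195562422394713
42,0.00267378004378727,0.00213959657559248
43,0.00292521273382695,0.00234085553889696
44,0.00320025129469326,0.00256102141509551
45,0.00350110449396168,0.00280186558973328
46,0.00383018629586374,0.00306532446473573
47,0.00419013463317552,0.0033535146443886
48,0.00458383183871247,0.00366874948193296
49,0.00501442687159948,0.00401355710131546
50,0.00548535948211715,0.004390700016773
51,0.00600038646758094,0.00480319648132477
52,0.00656361018024776,0.00525434370382505
53,0.00717950945646983,0.00574774308288839
54,0.00785297314400013,0.00628732761461581
55,0.00858933641118942,0.00687739163944967
56,0.0093944200274414,0.00752262310146445
57,0.0102745728082456,0.0082281385006836
58,0.0112367174198357,0.00899952072526822
59,0.0122883997373342,0.00984285995524481
60,0.0134378419453249,0.0107647978323093
61,0.0146939995601345,0.0117725750905486
62,0.016066622537524,0.0128740828399043
63,0.0175663206065354,0.0140779176869533
64,0.0192046329382322,0.0153934408649977
65,0.0209941022149777,0.0168308415262353
66,0.0229483531093554,0.0184012043213405
67,0.0250821751090476,0.0201165813542847
68,0.0274116095317261,0.0219900685504458
69,0.0299540404584848,0.0240358864114376
70,0.0327282891712395,0.0262694650475979
71,0.035754711503856,0.0287075332752058
72,0.0390552973029371,0.0313682114361954
73,0.0426537709358594,0.034271107438736
74,0.0465756914738019,0.0374374153222646
75,0.0508485508084462,0.0408900154143804
76,0.0555018675244885,0.0446535748627773
77,0.0605672738373656,0.0487546469857121
78,0.066078592307766,0.0532217674813791
79,0.072071898352857,0.0580855450614539
80,0.0785855637807419,0.0633787435181432
81,0.0856602756729825,0.0691363515884603
82,0.0933390239261674,0.0753956362357375
83,0.101667049637476,0.082196174119285
84,0.110691745286746,0.089579855063298
85,0.120462496342529,0.0975908502635445
86,0.131030452526868,0.106275536787764
87,0.142448215552403,0.115682368642722
88,0.154769428754317,0.125861683316646
89,0.168048252760734,0.136865431292247
90,0.182338710290578,0.14874681461138
91,0.197693882485536,0.16155981922768
92,0.214164939063063,0.17535862470533
93,0.231799985259294,0.190196873940264
94,0.250642710306484,0.206126785163997
95,0.27073082540659,0.223198088754847
96,0.292094284221391,0.241456772592708
97,0.314753286243674,0.260943622172855
98,0.338716073510979,0.281692545817086
99,0.363976544429639,0.303728681511616
100,0.390511725385984,0.32706629061986
101,0.41827916158705,0.351706455431557
102,0.447214313205651,0.377634612649347
103,0.477228071038077,0.404817973811745
104,0.508204536612872,0.433202906449197
105,0.539999243391491,0.462712376300773
106,0.572438025845124,0.493243580558343
107,0.605316768179648,0.524665933597272
108,0.63840227956307,0.55681959792354
109,0.671434542036905,0.589514781047406
110,1,1
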