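age,sex,annual_mortality
0,male,2.7999608003703713e-5
1,male,3.078997392258476e-5
2,male,3.3858415525278573e-5
3,male,3.723264363530987e-5
4,male,4.094313031133279e-5
5,male,4.5023383946629636e-5
6,male,4.9510251767137525e-5
7,male,5.444425245537676e-5
8,male,5.9869941897439105e-5
9,male,6.583631535073131e-5
10,male,7.239724965346639e-5
11,male,7.961198945960479e-5
12,male,8.754568187829825e-5
13,male,9.626996432932078e-5
14,male,1.0586361090436647e-4
15,male,1.1641324304967338e-4
16,male,1.2801411095830773e-4
17,male,1.4077095269660056e-4
18,male,1.5479893878111994e-4
19,male,1.7022471068817158e-4
20,male,1.8718752261293048e-4
21,male,2.058404967182348e-4
22,male,2.2635200311948989e-4
23,male,2.4890717696168796e-4
24,male,2.7370958616146357e-4
25,male,3.009830647167089e-4
26,male,3.3097372795343194e-4
27,male,3.639521876790397e-4
28,male,4.002159869704869e-4
29,male,4.4009227625074754e-4
30,male,4.839407544158236e-4
31,male,5.321569010833249e-4
32,male,5.851755285597449e-4
33,male,6.434746848867912e-4
34,male,7.075799423489348e-4
35,male,7.78069109121593e-4
36,male,8.555774053425891e-4
37,male,9.408031488198354e-4
38,male,0.001034513999868203
39,male,0.0011375538194318136
40,male,0.0012508501997177124
41,male,0.0013754227320775803
42,male,0.0015123920828442605
43,male,0.0016629899543069149
44,male,0.0018285700149993644
45,male,0.0020106198910329054
46,male,0.0022107743183251705
47,male,0.00243082956431262
48,male,0.0026727592370752173
49,male,0.002938731609773093
50,male,0.0032311285988956273
51,male,0.0035525665460318656
52,male,0.0039059189646662995
53,male,0.004294341425832737
54,male,0.004721298769241433
55,male,0.00519059483962625
56,male,0.00570640496137631
57,male,0.00627331137782372
58,male,0.00689634189458499
59,male,0.007581011978736507
60,male,0.008333370576922405
61,male,0.009160049925151736
62,male,0.010068319630365363
63,male,0.011066145307935038
64,male,0.01216225205903465
65,male,0.01336619306594844
66,male,0.014688423570236142
67,male,0.01614038047627664
68,male,0.017734567788685762
69,male,0.019484648043561426
70,male,0.021405539827049402
71,male,0.02351352138623175
72,male,0.025826340222027677
73,male,0.028363328405962895
74,male,0.031145523175702294
75,male,0.034195792130466085
76,male,0.03753896205803242
77,male,0.04120195006992078
78,male,0.04521389528923048
79,male,0.04960628881390783
80,male,0.054413099053228886
81,male,0.05967088879234239
82,male,0.06541891946364842
83,male,0.07169923707945447
84,male,0.0785567330936563
85,male,0.08603917209937184
86,male,0.09419717672697647
87,male,0.10308415838208851
88,male,0.11275618056511605
89,male,0.12327173946692915
90,male,0.13469144438311476
91,male,0.14707757830325063
92,male,0.16049351691828329
93,male,0.1750029824004513
94,male,0.19066910685491179
95,male,0.20755327959770065
96,male,0.22571375273927952
97,male,0.24520398139675337
98,male,0.26607067876965274
99,male,0.2883515729414883
100,male,0.3120728623465362
101,male,0.33724638116005423
102,male,0.3638665052235942
103,male,0.3919068542094172
104,male,0.42131687703910503
105,male,0.452018445167611
106,male,0.4839026216295269
107,male,0.5168268211562701
108,male,0.5506126253339625
109,male,0.5850445621389002
110,male,0.6198701947620517
0,female,1.5999872000738158e-5
1,female,1.7594386898966974e-5
2,female,1.934780639134548e-5
3,female,2.127596611334326e-5
4,female,2.3396279733689518e-5
5,female,2.5727896191818367e-5
6,female,2.829187260033894e-5
7,female,3.111136437283779e-5
8,female,3.4211834289754606e-5
9,female,3.7621282391042676e-5
10,female,4.1370498766402086e-5
11,female,4.549334152492701e-5
12,female,5.002704244871925e-5
13,female,5.501254308581949e-5
14,female,6.049486431303208e-5
15,female,6.6523512697092e-5
16,female,7.315292731635559e-5
17,female,8.04429710661303e-5
18,female,8.845947087221528e-5
19,female,9.727481167498553e-5
20,female,1.0696858952885524e-4
21,female,1.1762832969175463e-4
22,female,1.293502761604559e-4
23,female,1.4224025974884924e-4
24,female,1.5641465250493258e-4
25,female,1.7200141703710425e-4
26,female,1.8914126016245092e-4
27,female,2.0798890122364355e-4
28,female,2.2871446643657478e-4
29,female,2.515050217528625e-4
30,female,2.7656625794869605e-4
31,female,3.041243429970919e-4
32,female,3.344279582609966e-4
33,female,3.6775053666116e-4
34,female,4.043927227477262e-4
35,female,4.446850765529309e-4
36,female,4.889910452268165e-4
37,female,5.377102287936752e-4
38,female,5.912819689163351e-4
39,female,6.501892923457264e-4
40,female,7.149632437842834e-4
41,female,7.861876462212924e-4
42,female,8.645043304372768e-4
43,female,9.506188793381165e-4
44,female,0.0010453069371050283
45,female,0.0011494211378485497
46,female,0.0012638987135745738
47,female,0.001389769846827038
48,female,0.0015281668393986036
49,female,0.001680334175029441
50,female,0.0018476395610700358
51,female,0.002031586041695066
52,female,0.0022338252834477323
53,female,0.0024561721426923366
54,female,0.0027006206339613703
55,female,0.0029693614282284564
56,female,0.0032648010208000677
57,female,0.0035895827197983676
58,female,0.003946609618061703
59,female,0.004339069723671707
60,female,0.004770463437143824
61,female,0.005244633576476754
62,female,0.005765798164585667
63,female,0.006338586206933838
64,female,0.006968076700150538
65,female,0.007659841124717071
66,female,0.008419989685962914
67,female,0.009255221577061268
68,female,0.010172879544723124
69,female,0.011181009041961287
70,female,0.01228842225152249
71,female,0.01350476725700267
72,female,0.01484060262460618
73,female,0.016307477634965983
74,female,0.01791801836897411
75,female,0.019686019801256505
76,female,0.021626543986259295
77,female,0.023756024330748526
78,female,0.02609237582794599
79,female,0.02865511097675455
80,female,0.031465460917842636
81,female,0.03454650107895063
82,female,0.03792328032569836
83,female,0.04162295225121748
84,female,0.04567490679665587
85,female,0.05011089986229689
86,female,0.05496517793188427
87,female,0.06027459397599133
88,female,0.06607871000872756
89,female,0.07241988063065108
90,female,0.07934331068554146
91,female,0.08689707877828134
92,female,0.09513211683856448
93,female,0.10410213417065128
94,female,0.11386347251368711
95,female,0.12447487657599698
96,female,0.13599716234693282
97,female,0.14849276330585393
98,female,0.16202513255071382
99,female,0.17665797701616193
100,female,0.19245429855861562
101,female,0.20947521603908126
102,female,0.22777854300155143
103,female,0.2474170975861435
104,female,0.2684367254915483
105,female,0.2908740237686698
106,female,0.3147537637290577
107,female,0.34008602608289173
108,female,0.36686308137047186
109,female,0.39505607450553126
110,female,0.4246116042531376
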