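"let","alpha","beta"
0,0.1,0.05
5,0.163059066616789,0.05
10,0.210824110608268,0.05
15,0.24700446578816,0.05
20,0.274409823169945,0.05
25,0.295168425717903,0.05
30,0.310892343262234,0.05
35,0.322802662483854,0.05
40,0.331824313962307,0.05
45,0.338657900357786,0.05
50,0.34383410375425,0.05
55,0.347754897324561,0.05
60,0.350724761729714,0.05
65,0.352974330452686,0.05
70,0.354678300314269,0.05
75,0.355968998064258,0.05
80,0.356946656601174,0.05
85,0.357687198850369,0.05
90,0.358248133780238,0.05
95,0.358673022428914,0.05
100,0.358994860763737,0.05
105,0.359238642079347,0.05
110,0.359423297924877,0.05
115,0.35956316828862,0.05
120,0.359669115211652,0.05
125,0.359749366311309,0.05
130,0.359810153720815,0.05
135,0.359856198063762,0.05
140,0.359891075047903,0.05
145,0.359917493147175,0.05
150,0.359937503936131,0.05
155,0.359952661410957,0.05
160,0.359964142669572,0.05
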