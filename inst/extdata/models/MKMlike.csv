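"let","alpha","beta"
0,0.100013065769571,0.05
5,0.109258756114848,0.05
10,0.118053392447132,0.05
15,0.126449965474479,0.05
20,0.134537482396348,0.05
25,0.142488997086383,0.05
30,0.15066987757013,0.05
35,0.159875618811744,0.05
40,0.17182215847071,0.05
45,0.190002821831151,0.05
50,0.220526210865856,0.05
55,0.270552235423393,0.05
60,0.340150760282785,0.05
65,0.413849261898208,0.05
70,0.471823186853817,0.05
75,0.50820903945939,0.05
80,0.528706077226341,0.05
85,0.540315963213812,0.05
90,0.547518173014139,0.05
95,0.552609567146609,0.05
100,0.556666345265072,0.05
105,0.56017571985405,0.05
110,0.563357047536513,0.05
115,0.566310778382385,0.05
120,0.569085021363544,0.05
125,0.571704833465741,0.05
130,0.574185026165138,0.05
135,0.576535754457461,0.05
140,0.578764958503095,0.05
145,0.580879434979755,0.05
150,0.582885312045288,0.05
155,0.584788264566773,0.05
160,0.586593616005979,0.05
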