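age	qx
65	0.0121402804716296
66	0.0133223951993081
67	0.0146206851377405
68	0.0160463890791023
69	0.0176117957595467
70	0.0193303341063712
71	0.0212166695593958
72	0.0232868064905538
73	0.0255581966359903
74	0.028049853313921
75	0.0307824710226881
76	0.0337785497894066
77	0.037062523361707
78	0.04066088999356
79	0.0446023441599285
80	0.0489179070317113
81	0.0536410529386172
82	0.0588078283287445
83	0.0644569588846142
84	0.0706299394610195
85	0.0773711003559308
86	0.0847276420994814
87	0.0927496294392376
88	0.101489933510235
89	0.111004109312736
90	0.121350193600066
91	0.1325884061429
92	0.144780735150241
93	0.157990385490112
94	0.17228106640707
95	0.187716093875733
96	0.204357281822848
97	0.222263596536658
98	0.241489550093144
99	0.262083312093424
100	0.284084525054002
101	0.307521818140871
102	0.332410027373514
103	0.358747148744049
104	0.386511074630548
105	0.415656193967741
106	0.446109973036514
107	0.477769676000093
108	0.510499431099544
109	0.544127897129009
110	1
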