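"event","time","kind","is_cough","embedded","session_id"
1,17.3148060434964,"cough",TRUE,FALSE,"s01"
2,23.8370754132979,"word",FALSE,FALSE,"s01"
3,30.6861395347863,"cough",TRUE,FALSE,"s01"
4,37.5304476260673,"word",FALSE,FALSE,"s01"
5,44.241745518893,"sneeze",FALSE,FALSE,"s01"
6,51.9190959491301,"cough",TRUE,FALSE,"s01"
7,57.9365883146413,"cough",TRUE,FALSE,"s01"
8,65.4346665972378,"throat_clear",FALSE,FALSE,"s01"
9,72.4569922904018,"sneeze",FALSE,FALSE,"s01"
10,80.5050647840369,"word",FALSE,FALSE,"s01"
11,86.7577417762484,"cough",TRUE,FALSE,"s01"
12,93.5191122516524,"cough",TRUE,FALSE,"s01"
13,100.634672247153,"cough",TRUE,FALSE,"s01"
14,108.155428824341,"cough",TRUE,FALSE,"s01"
15,116.462292822544,"word",FALSE,FALSE,"s01"
16,123.640014522756,"cough",TRUE,FALSE,"s01"
17,131.478226428386,"word",FALSE,FALSE,"s01"
18,139.017487361655,"sneeze",FALSE,FALSE,"s01"
19,146.174997081561,"word",FALSE,FALSE,"s01"
20,153.860332746245,"throat_clear",FALSE,FALSE,"s01"
21,160.904031387297,"sneeze",FALSE,FALSE,"s01"
22,166.638710167725,"cough",TRUE,FALSE,"s01"
23,175.288891728921,"word",FALSE,FALSE,"s01"
24,181.346668232558,"cough",TRUE,FALSE,"s01"
25,188.0824375581,"word",FALSE,FALSE,"s01"
26,194.41421178435,"word",FALSE,FALSE,"s01"
27,200.490203467105,"sneeze",FALSE,FALSE,"s01"
28,206.90573813091,"cough",TRUE,FALSE,"s01"
29,212.646969628101,"cough",TRUE,FALSE,"s01"
30,218.736004259996,"sneeze",FALSE,FALSE,"s01"
31,226.037595617771,"cough",TRUE,FALSE,"s01"
32,234.211055141268,"word",FALSE,FALSE,"s01"
33,241.588108282816,"word",FALSE,FALSE,"s01"
34,249.785169729404,"word",FALSE,FALSE,"s01"
35,256.003948338795,"sneeze",FALSE,FALSE,"s01"
36,263.532916080253,"cough",TRUE,FALSE,"s01"
37,270.607334146881,"throat_clear",FALSE,FALSE,"s01"
38,278.107658972824,"word",FALSE,FALSE,"s01"
39,286.306601407798,"sneeze",FALSE,FALSE,"s01"
40,292.611778643448,"throat_clear",FALSE,FALSE,"s01"
41,298.679559240537,"cough",TRUE,FALSE,"s01"
42,322.235771584976,"cough",TRUE,TRUE,"s01"
43,346.837431032863,"cough",TRUE,TRUE,"s01"
44,374.673539913772,"cough",TRUE,FALSE,"s01"
45,380.231751248892,"sneeze",FALSE,FALSE,"s01"
46,386.657576596644,"throat_clear",FALSE,FALSE,"s01"
47,393.487754905503,"cough",TRUE,FALSE,"s01"
48,401.539978769468,"sneeze",FALSE,FALSE,"s01"
1,18.8764346989337,"cough",TRUE,FALSE,"s02"
2,27.0423488156404,"word",FALSE,FALSE,"s02"
3,34.4462378135417,"cough",TRUE,FALSE,"s02"
4,41.1070183285978,"cough",TRUE,FALSE,"s02"
5,49.2347910551354,"word",FALSE,FALSE,"s02"
6,72.6454572340473,"cough",TRUE,TRUE,"s02"
7,97.612029979052,"cough",TRUE,TRUE,"s02"
8,124.655978516489,"sneeze",FALSE,FALSE,"s02"
9,132.665520478599,"throat_clear",FALSE,FALSE,"s02"
10,138.405044579506,"cough",TRUE,FALSE,"s02"
11,146.102548482921,"sneeze",FALSE,FALSE,"s02"
12,152.217138722306,"cough",TRUE,FALSE,"s02"
13,160.568076964421,"cough",TRUE,FALSE,"s02"
14,166.106377045251,"cough",TRUE,FALSE,"s02"
15,173.191624136176,"sneeze",FALSE,FALSE,"s02"
16,180.097899801051,"sneeze",FALSE,FALSE,"s02"
17,186.525131266378,"cough",TRUE,FALSE,"s02"
18,195.071876234841,"sneeze",FALSE,FALSE,"s02"
19,203.382491525495,"sneeze",FALSE,FALSE,"s02"
20,209.477103376435,"throat_clear",FALSE,FALSE,"s02"
21,214.785852537118,"cough",TRUE,FALSE,"s02"
22,222.037772154855,"word",FALSE,FALSE,"s02"
23,227.796319364104,"word",FALSE,FALSE,"s02"
24,236.124161460763,"word",FALSE,FALSE,"s02"
25,243.585438588914,"cough",TRUE,FALSE,"s02"
26,249.998152282601,"throat_clear",FALSE,FALSE,"s02"
27,257.057471152395,"cough",TRUE,FALSE,"s02"
28,265.27369296425,"word",FALSE,FALSE,"s02"
29,271.297991926922,"word",FALSE,FALSE,"s02"
30,277.825107899075,"cough",TRUE,FALSE,"s02"
31,284.038182840543,"cough",TRUE,FALSE,"s02"
32,290.773078520643,"word",FALSE,FALSE,"s02"
33,298.614089832827,"sneeze",FALSE,FALSE,"s02"
34,305.315184899839,"throat_clear",FALSE,FALSE,"s02"
35,312.268318096967,"word",FALSE,FALSE,"s02"
36,319.239644126221,"sneeze",FALSE,FALSE,"s02"
37,326.139058027463,"cough",TRUE,FALSE,"s02"
38,334.601828285726,"cough",TRUE,FALSE,"s02"
39,342.103906936292,"sneeze",FALSE,FALSE,"s02"
40,349.858318280987,"word",FALSE,FALSE,"s02"
41,358.170767963678,"throat_clear",FALSE,FALSE,"s02"
42,366.114528023219,"sneeze",FALSE,FALSE,"s02"
43,371.982873708336,"cough",TRUE,FALSE,"s02"
44,378.676859610993,"word",FALSE,FALSE,"s02"
45,385.639135265909,"word",FALSE,FALSE,"s02"
46,392.87343581398,"cough",TRUE,FALSE,"s02"
47,399.2364859452,"cough",TRUE,FALSE,"s02"
48,405.459278114512,"word",FALSE,FALSE,"s02"
1,18.4704090298619,"cough",TRUE,FALSE,"s03"
2,27.0809395122807,"word",FALSE,FALSE,"s03"
3,34.8357286957093,"cough",TRUE,FALSE,"s03"
4,40.6766558313742,"cough",TRUE,FALSE,"s03"
5,48.75713459244,"word",FALSE,FALSE,"s03"
6,72.5849261202849,"cough",TRUE,TRUE,"s03"
7,96.8478854392189,"cough",TRUE,TRUE,"s03"
8,124.517381483503,"sneeze",FALSE,FALSE,"s03"
9,132.580615984136,"throat_clear",FALSE,FALSE,"s03"
10,138.182626342727,"cough",TRUE,FALSE,"s03"
11,146.324742112635,"sneeze",FALSE,FALSE,"s03"
12,151.987544646952,"cough",TRUE,FALSE,"s03"
13,160.04141562148,"cough",TRUE,FALSE,"s03"
14,165.760150333494,"cough",TRUE,FALSE,"s03"
15,173.069154711906,"sneeze",FALSE,FALSE,"s03"
16,180.160695231007,"sneeze",FALSE,FALSE,"s03"
17,187.182979156077,"cough",TRUE,FALSE,"s03"
18,194.690062934533,"sneeze",FALSE,FALSE,"s03"
19,203.371892383788,"sneeze",FALSE,FALSE,"s03"
20,208.712584582064,"throat_clear",FALSE,FALSE,"s03"
21,214.594088850636,"cough",TRUE,FALSE,"s03"
22,222.030156581383,"word",FALSE,FALSE,"s03"
23,227.270247901091,"word",FALSE,FALSE,"s03"
24,235.61006280533,"word",FALSE,FALSE,"s03"
25,243.782534253132,"cough",TRUE,FALSE,"s03"
26,249.784340109723,"throat_clear",FALSE,FALSE,"s03"
27,257.471905849641,"cough",TRUE,FALSE,"s03"
28,264.905780002149,"word",FALSE,FALSE,"s03"
29,271.990702586155,"word",FALSE,FALSE,"s03"
30,277.411584498873,"cough",TRUE,FALSE,"s03"
31,284.42102563763,"cough",TRUE,FALSE,"s03"
32,290.414161413768,"word",FALSE,FALSE,"s03"
33,298.826816593483,"sneeze",FALSE,FALSE,"s03"
34,304.885549698025,"throat_clear",FALSE,FALSE,"s03"
35,311.901533848699,"word",FALSE,FALSE,"s03"
36,319.366383475671,"sneeze",FALSE,FALSE,"s03"
37,326.147825921699,"cough",TRUE,FALSE,"s03"
38,334.615885551786,"cough",TRUE,FALSE,"s03"
39,341.75021323706,"sneeze",FALSE,FALSE,"s03"
40,349.552744704392,"word",FALSE,FALSE,"s03"
41,357.523012597393,"throat_clear",FALSE,FALSE,"s03"
42,365.358451190684,"sneeze",FALSE,FALSE,"s03"
43,372.111874283384,"cough",TRUE,FALSE,"s03"
44,378.572315408429,"word",FALSE,FALSE,"s03"
45,385.973688007984,"word",FALSE,FALSE,"s03"
46,392.356643519178,"cough",TRUE,FALSE,"s03"
47,399.003766556876,"cough",TRUE,FALSE,"s03"
48,404.862573524378,"word",FALSE,FALSE,"s03"
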