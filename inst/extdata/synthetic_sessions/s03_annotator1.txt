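18.461049	18.461049	3
27.076768	27.076768	0
34.841553	34.841553	3
40.667625	40.667625	3
48.806947	48.806947	0
72.609954	72.609954	3
96.816730	96.816730	3
124.478256	124.478256	0
132.604997	132.604997	0
138.144134	138.144134	3
146.374524	146.374524	0
152.015357	152.015357	3
160.032234	160.032234	1
165.737974	165.737974	3
173.114824	173.114824	0
180.136148	180.136148	0
187.144990	187.144990	3
194.694562	194.694562	0
203.389245	203.389245	0
208.700018	208.700018	0
214.558800	214.558800	3
222.077057	222.077057	0
227.227172	227.227172	0
235.620302	235.620302	0
243.752021	243.752021	3
249.790757	249.790757	0
257.436666	257.436666	3
264.938189	264.938189	0
271.973655	271.973655	0
277.409194	277.409194	3
284.390004	284.390004	3
290.416105	290.416105	0
298.826326	298.826326	0
304.849716	304.849716	0
311.926862	311.926862	0
319.317476	319.317476	0
326.115622	326.115622	3
334.577253	334.577253	3
341.753884	341.753884	0
349.557287	349.557287	0
357.475105	357.475105	0
365.323524	365.323524	0
372.117508	372.117508	3
378.597768	378.597768	0
385.989822	385.989822	0
392.383223	392.383223	3
398.968051	398.968051	3
404.871178	404.871178	0
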