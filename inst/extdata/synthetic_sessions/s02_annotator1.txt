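18.845723	18.845723	3
27.002113	27.002113	0
34.479149	34.479149	3
41.137605	41.137605	3
49.212718	49.212718	0
72.640360	72.640360	3
97.624618	97.624618	3
124.643071	124.643071	0
132.653752	132.653752	0
138.446493	138.446493	3
146.091578	146.091578	0
152.174168	152.174168	3
160.588828	160.588828	3
166.125677	166.125677	3
173.151239	173.151239	0
180.051590	180.051590	0
186.515225	186.515225	2
195.023030	195.023030	0
203.389281	203.389281	1
209.521598	209.521598	0
214.770183	214.770183	3
222.012222	222.012222	0
227.800487	227.800487	0
236.085932	236.085932	0
243.572929	243.572929	3
249.980903	249.980903	0
257.102192	257.102192	3
265.314750	265.314750	0
271.324236	271.324236	0
277.850915	277.850915	3
284.088032	284.088032	3
290.781119	290.781119	0
298.585418	298.585418	0
305.278540	305.278540	0
312.297546	312.297546	0
319.287835	319.287835	0
326.187263	326.187263	3
334.564373	334.564373	3
342.115735	342.115735	0
349.894137	349.894137	0
358.134707	358.134707	0
366.101186	366.101186	0
371.948587	371.948587	3
378.671644	378.671644	0
385.637723	385.637723	0
392.918456	392.918456	3
399.276961	399.276961	3
405.503295	405.503295	0
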