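18.520340	18.520340	3
27.032803	27.032803	0
34.857517	34.857517	3
40.680391	40.680391	3
48.746281	48.746281	0
72.584854	72.584854	3
96.896878	96.896878	3
124.516859	124.516859	0
132.628284	132.628284	0
138.207419	138.207419	3
146.343193	146.343193	0
151.987019	151.987019	3
159.996867	159.996867	3
165.788264	165.788264	3
173.053784	173.053784	0
180.112913	180.112913	0
187.195257	187.195257	3
194.653025	194.653025	0
203.339877	203.339877	0
208.726223	208.726223	0
214.560962	214.560962	3
222.016365	222.016365	0
227.242340	227.242340	0
235.642824	235.642824	0
243.732899	243.732899	3
249.750092	249.750092	0
257.515626	257.515626	2
264.932324	264.932324	0
272.022866	272.022866	0
277.386765	277.386765	3
284.382781	284.382781	3
290.377446	290.377446	0
298.818753	298.818753	0
304.872137	304.872137	0
311.866011	311.866011	0
319.368369	319.368369	0
326.172405	326.172405	3
334.576864	334.576864	3
341.737173	341.737173	0
349.524988	349.524988	0
357.562710	357.562710	0
365.319086	365.319086	0
372.145774	372.145774	3
378.606852	378.606852	0
385.926380	385.926380	0
392.383178	392.383178	3
398.981249	398.981249	3
404.827665	404.827665	0
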