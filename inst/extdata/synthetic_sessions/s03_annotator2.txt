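18.491136	18.491136	3
27.072949	27.072949	0
34.884818	34.884818	3
40.635258	40.635258	3
48.762046	48.762046	0
72.572795	72.572795	3
96.836657	96.836657	3
124.499912	124.499912	0
132.630262	132.630262	0
138.207267	138.207267	3
146.352721	146.352721	0
152.028012	152.028012	3
160.058088	160.058088	3
165.779333	165.779333	3
173.113762	173.113762	0
180.123655	180.123655	0
187.228036	187.228036	3
194.735327	194.735327	0
203.330678	203.330678	0
208.746968	208.746968	0
214.619801	214.619801	0
222.039000	222.039000	0
227.250748	227.250748	0
235.561430	235.561430	0
243.764853	243.764853	3
249.751329	249.751329	0
257.443782	257.443782	3
264.903046	264.903046	0
271.941506	271.941506	0
277.439261	277.439261	3
284.450168	284.450168	3
290.376063	290.376063	0
298.796179	298.796179	0
304.935484	304.935484	0
311.941857	311.941857	0
319.316916	319.316916	0
326.170205	326.170205	3
334.606560	334.606560	3
341.702505	341.702505	0
349.542505	349.542505	0
357.490766	357.490766	0
365.333806	365.333806	0
372.153239	372.153239	3
378.559802	378.559802	0
385.953665	385.953665	0
392.383751	392.383751	3
398.955198	398.955198	3
404.831671	404.831671	0
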