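18.903784	18.903784	3
27.001570	27.001570	0
34.397862	34.397862	3
41.090369	41.090369	3
49.208976	49.208976	0
72.674664	72.674664	3
97.611669	97.611669	3
124.657366	124.657366	0
132.622761	132.622761	0
138.389558	138.389558	3
146.128181	146.128181	0
152.205651	152.205651	3
160.518769	160.518769	3
166.128221	166.128221	3
173.197321	173.197321	0
180.054908	180.054908	0
186.509913	186.509913	3
195.063177	195.063177	0
203.363657	203.363657	0
209.500860	209.500860	0
214.774687	214.774687	3
222.049715	222.049715	0
227.808673	227.808673	0
236.154403	236.154403	0
243.600845	243.600845	3
250.016098	250.016098	0
257.048547	257.048547	3
265.290018	265.290018	0
271.250704	271.250704	0
277.856701	277.856701	3
283.995687	283.995687	3
290.813175	290.813175	0
298.571173	298.571173	0
305.284297	305.284297	0
312.296011	312.296011	0
319.209957	319.209957	0
326.129434	326.129434	3
334.596446	334.596446	3
342.114536	342.114536	0
349.865963	349.865963	0
358.126719	358.126719	0
366.082795	366.082795	0
371.962486	371.962486	3
378.664468	378.664468	0
385.660445	385.660445	0
392.835951	392.835951	3
399.229409	399.229409	3
405.412316	405.412316	0
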