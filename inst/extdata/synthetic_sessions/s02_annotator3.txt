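18.871852	18.871852	3
27.071780	27.071780	0
34.443365	34.443365	3
41.080657	41.080657	3
49.273495	49.273495	0
72.608053	72.608053	3
97.588961	97.588961	3
124.694224	124.694224	0
132.690572	132.690572	0
138.364814	138.364814	3
146.134105	146.134105	0
152.252978	152.252978	3
160.529793	160.529793	3
166.070117	166.070117	3
173.196450	173.196450	0
180.053803	180.053803	0
186.524684	186.524684	3
195.022618	195.022618	0
203.417321	203.417321	0
209.433378	209.433378	0
214.817837	214.817837	3
222.041708	222.041708	0
227.796221	227.796221	0
236.076384	236.076384	0
243.590848	243.590848	3
250.020142	250.020142	0
257.031043	257.031043	3
265.304881	265.304881	0
271.290139	271.290139	0
277.831599	277.831599	3
284.003352	284.003352	3
290.742558	290.742558	0
298.580768	298.580768	0
305.348696	305.348696	0
312.229426	312.229426	0
319.216451	319.216451	0
326.168906	326.168906	3
334.581721	334.581721	3
342.140664	342.140664	0
349.812261	349.812261	0
358.154750	358.154750	0
366.095488	366.095488	0
371.945819	371.945819	3
378.664243	378.664243	0
385.635632	385.635632	0
392.828097	392.828097	3
399.285238	399.285238	3
405.500123	405.500123	0
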