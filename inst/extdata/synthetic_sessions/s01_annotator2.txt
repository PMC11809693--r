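17.271878	17.271878	3
23.808215	23.808215	0
30.691102	30.691102	3
37.528646	37.528646	0
44.207693	44.207693	0
51.884054	51.884054	3
57.936516	57.936516	3
65.478723	65.478723	1
72.440415	72.440415	0
80.473908	80.473908	0
86.734713	86.734713	3
93.522187	93.522187	3
100.586817	100.586817	3
108.185305	108.185305	3
116.423326	116.423326	0
123.643994	123.643994	3
131.485350	131.485350	0
139.029383	139.029383	0
146.196482	146.196482	0
153.822663	153.822663	0
160.885136	160.885136	0
166.683284	166.683284	3
175.288894	175.288894	0
181.310191	181.310191	3
188.119363	188.119363	0
194.384717	194.384717	0
200.532708	200.532708	0
206.944413	206.944413	3
212.610599	212.610599	3
218.764539	218.764539	0
226.032926	226.032926	3
234.174629	234.174629	0
241.626630	241.626630	0
249.768841	249.768841	0
255.985876	255.985876	0
263.523294	263.523294	3
270.605242	270.605242	0
278.094449	278.094449	0
286.303170	286.303170	0
292.566768	292.566768	0
298.648295	298.648295	3
322.284038	322.284038	3
346.820258	346.820258	3
374.640640	374.640640	3
380.230577	380.230577	0
386.609445	386.609445	0
393.471703	393.471703	3
401.492945	401.492945	0
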