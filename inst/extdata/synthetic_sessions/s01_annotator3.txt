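17.351529	17.351529	3
23.860246	23.860246	0
30.667666	30.667666	3
37.519093	37.519093	0
44.224990	44.224990	0
51.878074	51.878074	3
57.962294	57.962294	3
65.444963	65.444963	0
72.421532	72.421532	0
80.458317	80.458317	0
86.756119	86.756119	3
93.513569	93.513569	3
100.590711	100.590711	3
108.138179	108.138179	3
116.500136	116.500136	0
123.683075	123.683075	3
131.467444	131.467444	0
138.983372	138.983372	0
146.156992	146.156992	0
153.841029	153.841029	0
160.864813	160.864813	0
166.686644	166.686644	3
175.288582	175.288582	0
181.305976	181.305976	3
188.053615	188.053615	0
194.457262	194.457262	0
200.469888	200.469888	0
206.921060	206.921060	3
212.687077	212.687077	3
218.785084	218.785084	0
226.030629	226.030629	3
234.200433	234.200433	0
241.552299	241.552299	0
249.763150	249.763150	0
256.010431	256.010431	0
263.576430	263.576430	3
270.593174	270.593174	0
278.141860	278.141860	0
286.328842	286.328842	0
292.636852	292.636852	0
298.721958	298.721958	3
322.186009	322.186009	3
346.803474	346.803474	3
374.663467	374.663467	3
380.249283	380.249283	0
386.655614	386.655614	0
393.491138	393.491138	3
401.521674	401.521674	0
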