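17.272031	17.272031	3
23.792388	23.792388	0
30.689327	30.689327	3
37.491678	37.491678	0
44.266064	44.266064	0
51.942227	51.942227	3
57.975100	57.975100	3
65.436378	65.436378	0
72.492185	72.492185	0
80.499344	80.499344	0
86.723530	86.723530	3
93.513345	93.513345	1
100.681446	100.681446	3
108.153888	108.153888	3
116.437539	116.437539	0
123.615984	123.615984	3
131.482428	131.482428	0
139.032475	139.032475	0
146.158639	146.158639	0
153.816428	153.816428	0
160.899162	160.899162	0
166.672586	166.672586	3
175.296355	175.296355	0
181.332003	181.332003	3
188.087180	188.087180	0
194.453484	194.453484	0
200.489203	200.489203	0
206.872901	206.872901	3
212.651273	212.651273	3
218.782151	218.782151	0
226.018964	226.018964	3
234.243107	234.243107	0
241.568814	241.568814	0
249.753715	249.753715	0
255.958783	255.958783	0
263.507483	263.507483	3
270.592445	270.592445	0
278.073561	278.073561	0
286.287011	286.287011	0
292.563533	292.563533	0
298.729215	298.729215	3
322.266211	322.266211	3
346.796089	346.796089	3
374.710533	374.710533	3
380.237210	380.237210	0
386.649714	386.649714	0
393.444519	393.444519	3
401.546123	401.546123	0
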