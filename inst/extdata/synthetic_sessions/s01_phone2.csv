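device_id,timestamp,score
s01_phone2,-2.621034,0.918842
s01_phone2,10.705064,0.941170
s01_phone2,17.461236,0.188598
s01_phone2,32.029340,0.956203
s01_phone2,38.074226,0.901287
s01_phone2,60.524942,0.060876
s01_phone2,66.721131,0.973477
s01_phone2,73.359287,0.886653
s01_phone2,80.553904,0.969415
s01_phone2,88.252398,0.908633
s01_phone2,103.701264,0.934728
s01_phone2,146.679524,0.972077
s01_phone2,161.295562,0.941553
s01_phone2,186.817815,0.921248
s01_phone2,192.692674,0.904382
s01_phone2,205.979039,0.899831
s01_phone2,243.390039,0.904651
s01_phone2,250.515494,0.020306
s01_phone2,278.615839,0.953541
s01_phone2,302.320774,0.971101
s01_phone2,326.975367,0.877372
s01_phone2,354.734874,0.947599
s01_phone2,366.510594,0.132908
s01_phone2,373.468122,0.985880
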