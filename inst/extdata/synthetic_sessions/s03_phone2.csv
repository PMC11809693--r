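device_id,timestamp,score
s03_phone2,44.620875,0.962407
s03_phone2,61.123837,0.985941
s03_phone2,66.905224,0.968229
s03_phone2,98.851506,0.978170
s03_phone2,122.978973,0.885841
s03_phone2,150.568191,0.050215
s03_phone2,164.393459,0.910227
s03_phone2,178.237981,0.907976
s03_phone2,186.250455,0.923956
s03_phone2,192.092733,0.908067
s03_phone2,199.241716,0.014846
s03_phone2,213.237097,0.986201
s03_phone2,229.586362,0.042403
s03_phone2,240.739831,0.973568
s03_phone2,283.741417,0.986093
s03_phone2,303.520389,0.973508
s03_phone2,310.510404,0.971934
s03_phone2,324.838016,0.065133
s03_phone2,352.184640,0.998477
s03_phone2,360.664699,0.889046
s03_phone2,375.484641,0.396711
s03_phone2,398.347559,0.976962
s03_phone2,412.216000,0.535488
s03_phone2,416.858604,0.876639
s03_phone2,418.423994,0.995751
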