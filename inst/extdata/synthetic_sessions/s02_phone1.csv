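device_id,timestamp,score
s02_phone1,-9.782447,0.978298
s02_phone1,5.870562,0.865525
s02_phone1,12.343870,0.939266
s02_phone1,68.840554,0.856175
s02_phone1,117.435438,0.031719
s02_phone1,123.459087,0.974119
s02_phone1,131.761178,0.970336
s02_phone1,137.169239,0.851608
s02_phone1,151.208121,0.045123
s02_phone1,157.802353,0.941037
s02_phone1,174.473117,0.003987
s02_phone1,186.127289,0.957452
s02_phone1,193.139720,0.064281
s02_phone1,214.802673,0.912122
s02_phone1,228.293829,0.864738
s02_phone1,249.060416,0.927444
s02_phone1,255.289969,0.949068
s02_phone1,290.536086,0.084983
s02_phone1,297.363028,0.906277
s02_phone1,305.813566,0.994822
s02_phone1,321.110942,0.019006
s02_phone1,364.066663,0.936326
s02_phone1,370.626818,0.969811
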