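device_id,timestamp,score
s03_phone1,42.400104,0.999709
s03_phone1,58.753766,0.867081
s03_phone1,64.847440,0.983315
s03_phone1,96.753055,0.924031
s03_phone1,120.859195,0.931085
s03_phone1,156.706538,0.010196
s03_phone1,162.305516,0.996975
s03_phone1,170.570265,0.315723
s03_phone1,176.117992,0.950140
s03_phone1,184.312803,0.961615
s03_phone1,189.863285,0.920208
s03_phone1,211.335878,0.876191
s03_phone1,227.550134,0.136545
s03_phone1,238.664409,0.998659
s03_phone1,268.072582,0.966196
s03_phone1,273.935100,0.252058
s03_phone1,281.675620,0.850437
s03_phone1,301.522728,0.925584
s03_phone1,308.628359,0.949332
s03_phone1,314.492028,0.132713
s03_phone1,350.303502,0.952320
s03_phone1,358.750701,0.950843
s03_phone1,365.951800,0.065819
s03_phone1,396.236498,0.951606
s03_phone1,416.452680,0.956006
s03_phone1,423.027961,0.866604
s03_phone1,428.844933,0.314137
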