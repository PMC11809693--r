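device_id,timestamp,score
s01_phone1,-1.716108,0.854579
s01_phone1,4.987462,0.059272
s01_phone1,11.712433,0.932911
s01_phone1,33.142587,0.901855
s01_phone1,38.752977,0.875436
s01_phone1,68.038466,0.942720
s01_phone1,74.624533,0.963948
s01_phone1,81.880899,0.992660
s01_phone1,89.349194,0.925070
s01_phone1,104.773994,0.986175
s01_phone1,127.177938,0.047900
s01_phone1,142.006045,0.169789
s01_phone1,147.685347,0.915018
s01_phone1,162.295395,0.940326
s01_phone1,175.524787,0.312475
s01_phone1,187.999144,0.885005
s01_phone1,193.671224,0.759740
s01_phone1,199.799582,0.267656
s01_phone1,206.968038,0.981340
s01_phone1,222.610020,0.079811
s01_phone1,230.987918,0.013631
s01_phone1,244.771954,0.965779
s01_phone1,267.316021,0.254558
s01_phone1,279.727597,0.866417
s01_phone1,303.423723,0.935377
s01_phone1,327.901082,0.930337
s01_phone1,355.745360,0.969347
s01_phone1,374.539916,0.965024
s01_phone1,466.275622,0.904469
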