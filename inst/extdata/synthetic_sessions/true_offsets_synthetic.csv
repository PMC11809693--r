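"session_id","device_id","offset"
"s01","s01_phone1",18.8854554109275
"s01","s01_phone2",20.0318002514541
"s02","s02_phone1",28.7634088005871
"s02","s02_phone2",-23.2131738960743
"s03","s03_phone1",-24.0781337348744
"s03","s03_phone2",-26.1659445008263
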