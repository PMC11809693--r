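device_id,timestamp,score
s02_phone2,41.960640,0.980232
s02_phone2,57.728822,0.883188
s02_phone2,64.260274,0.957816
s02_phone2,95.984322,0.924538
s02_phone2,120.830555,0.967194
s02_phone2,147.941962,0.051518
s02_phone2,161.774328,0.925591
s02_phone2,175.456875,0.980629
s02_phone2,209.845978,0.998816
s02_phone2,218.306120,0.063773
s02_phone2,237.847859,0.942766
s02_phone2,266.800853,0.870508
s02_phone2,280.342459,0.606036
s02_phone2,301.087227,0.883223
s02_phone2,307.233968,0.990051
s02_phone2,349.230462,0.971211
s02_phone2,357.879642,0.988071
s02_phone2,365.225435,0.077838
s02_phone2,395.070865,0.990969
s02_phone2,408.911802,0.064732
s02_phone2,415.963329,0.815786
s02_phone2,422.474096,0.941945
s02_phone2,518.046275,0.852395
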