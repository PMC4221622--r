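group,lat,lon
Blackfoot,48.7,-112.8
Sarsi,51.4,-113.6
GrosVentre,48.2,-108.6
Assiniboine,48.7,-105.4
Crow,45.6,-107.6
Cheyenne,41.6,-104.1
Arapaho,40.6,-105.6
Teton,44.1,-101.6
Kiowa,35.6,-99.2
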