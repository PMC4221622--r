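group1,group2
Blackfoot,Sarsi
Blackfoot,GrosVentre
Blackfoot,Crow
GrosVentre,Assiniboine
GrosVentre,Crow
Assiniboine,Teton
Crow,Teton
Crow,Cheyenne
Cheyenne,Teton
Cheyenne,Arapaho
Cheyenne,Kiowa
Arapaho,Kiowa
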