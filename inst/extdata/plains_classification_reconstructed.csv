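group,family,subgroup
Blackfoot,Algonquian,
Sarsi,Athabaskan,
GrosVentre,Algonquian,Arapahoan
Assiniboine,Siouan,Dakotan
Crow,Siouan,
Cheyenne,Algonquian,
Arapaho,Algonquian,Arapahoan
Teton,Siouan,Dakotan
Kiowa,KiowaTanoan,
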