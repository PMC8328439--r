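prey,d13C,d15N
Pleuronectes platessa,-17.0,15.0
Solea solea,-17.5,15.2
Microchirus variegatus,-16.2,13.1
Trisopterus luscus,-17.8,14.9
Merlangius merlangus,-18.6,15.4
Loligo vulgaris,-18.2,14.6
Callionymus lyra,-17.3,14.5
Clupea harengus (0-20 m),-17.6,14.2
Clupea harengus (20-38 m),-19.6,12.9
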