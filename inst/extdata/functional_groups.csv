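taxon,group
Pleuronectes platessa,benthic_flatfish
Platichthys flesus,benthic_flatfish
Solea solea,benthic_flatfish
Pegusa lascaris,benthic_flatfish
Buglossidium luteum,benthic_flatfish
Microchirus variegatus,benthic_flatfish
Und. Bothidae,benthic_flatfish
Scophtalmus spp.,benthic_flatfish
Phrynorhombus norvegicus,benthic_flatfish
Und. Gobidae,benthic_nonflatfish
Trachinus draco,benthic_nonflatfish
Callionymus lyra,benthic_nonflatfish
Und. Triglidae,benthic_nonflatfish
Merlangius merlangus,demersal_fish
Trisopterus spp.,demersal_fish
Gadus morhua,demersal_fish
Pollachius spp.,demersal_fish
Melanogrammus aeglefinus,demersal_fish
Und. Sandeels,demersal_fish
Dicentrarchus labrax,demersal_fish
Und. Mullets,demersal_fish
Clupea harengus,pelagic_fish
Sardina pilchardus,pelagic_fish
Sprattus sprattus,pelagic_fish
Belone belone,pelagic_fish
Trachurus trachurus,pelagic_fish
Loligo spp.,pelagic_squid
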