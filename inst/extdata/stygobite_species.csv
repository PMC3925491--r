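species,order_group,kp_occurrence
Islamia moquiniana,Mesogastropoda,3-6;97-103
Fabaeformiscandona wegelini,Ostracoda,97-103
Parabathynella cf. stygia,Bathynellacea,96-97
Crangonyx subterraneus,Amphipoda,96-97
Niphargopsis casparyi,Amphipoda,4-5;96-103;109-110
Niphargus fontanus,Amphipoda,4-5;96-98;109-110
Niphargus kochianus,Amphipoda,4-6;97
Niphargus rhenorhodanensis,Amphipoda,96-103;109-110
Salentinella juberthiae,Amphipoda,96-97;109-110
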