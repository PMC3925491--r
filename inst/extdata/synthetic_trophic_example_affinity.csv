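species,class,weight
Berula erecta,1,0.55
Berula erecta,2,0.30
Berula erecta,3,0.10
Berula erecta,4,0.05
Mentha aquatica,1,0.25
Mentha aquatica,2,0.45
Mentha aquatica,3,0.20
Mentha aquatica,4,0.10
Potamogeton coloratus,1,0.70
Potamogeton coloratus,2,0.20
Potamogeton coloratus,3,0.07
Potamogeton coloratus,4,0.03
Lemna minor,1,0.05
Lemna minor,2,0.15
Lemna minor,3,0.40
Lemna minor,4,0.40
Ceratophyllum demersum,1,0.02
Ceratophyllum demersum,2,0.08
Ceratophyllum demersum,3,0.45
Ceratophyllum demersum,4,0.45
Elodea canadensis,1,0.10
Elodea canadensis,2,0.30
Elodea canadensis,3,0.40
Elodea canadensis,4,0.20
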