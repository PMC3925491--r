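site_id,species,bb_code
W_demo,Berula erecta,2
W_demo,Mentha aquatica,1
W_demo,Potamogeton coloratus,3
W_demo,Lemna minor,+
W_demo,Ceratophyllum demersum,1
W_demo,Elodea canadensis,r
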