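metabolite,parent
Aldicarb sulfone,Aldicarb
Aldicarb sulfoxide,Aldicarb
Deethylatrazine,Atrazine
2-Chloro-4-isopropylamino-6-amino-s-triazine,Atrazine
"2,6-Diethylaniline",Alachlor
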