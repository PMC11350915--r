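species,site,call_structure,diel,seasonal,total
Amietia desaegeri,sandi,0.12,0.04,0.00,0.06
Arthroleptis schubotzi,malalo,0.12,0.00,0.00,0.05
Hyperolius castaneus,sandi,0.14,0.65,0.55,0.38
Hyperolius castaneus,malalo,0.13,0.43,0.83,0.31
Hyperolius glandicolor,sandi,0.11,0.35,0.08,0.17
Hyperolius glandicolor,malalo,0.11,0.43,0.26,0.29
Leptopelis karissimbensis,sandi,0.07,0.30,0.02,0.12
Leptopelis karissimbensis,malalo,0.08,0.27,0.19,0.14
Leptopelis kivuensis,sandi,0.14,0.31,0.11,0.24
Leptopelis kivuensis,malalo,0.14,0.30,0.38,0.26
Phrynobatrachus bequaerti,sandi,0.35,0.63,0.25,0.35
Phrynobatrachus bequaerti,malalo,0.21,0.64,0.55,0.28
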