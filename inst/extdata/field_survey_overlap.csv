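site,species_a,species_b,overlap
sandi,Amietia desaegeri,Hyperolius castaneus,0.2398
sandi,Amietia desaegeri,Hyperolius glandicolor,0.1211
sandi,Amietia desaegeri,Leptopelis karissimbensis,0.2822
sandi,Amietia desaegeri,Leptopelis kivuensis,0.2679
sandi,Amietia desaegeri,Phrynobatrachus bequaerti,0.0741
sandi,Hyperolius castaneus,Hyperolius glandicolor,0.2884
sandi,Hyperolius castaneus,Leptopelis karissimbensis,0.3214
sandi,Hyperolius castaneus,Leptopelis kivuensis,0.4050
sandi,Hyperolius castaneus,Phrynobatrachus bequaerti,0.3856
sandi,Hyperolius glandicolor,Leptopelis karissimbensis,0.4301
sandi,Hyperolius glandicolor,Leptopelis kivuensis,0.4596
sandi,Hyperolius glandicolor,Phrynobatrachus bequaerti,0.4535
sandi,Leptopelis karissimbensis,Leptopelis kivuensis,0.7389
sandi,Leptopelis karissimbensis,Phrynobatrachus bequaerti,0.3895
sandi,Leptopelis kivuensis,Phrynobatrachus bequaerti,0.3710
malalo,Arthroleptis schubotzi,Hyperolius castaneus,0.2585
malalo,Arthroleptis schubotzi,Hyperolius glandicolor,0.1799
malalo,Arthroleptis schubotzi,Leptopelis karissimbensis,0.2388
malalo,Arthroleptis schubotzi,Leptopelis kivuensis,0.3738
malalo,Arthroleptis schubotzi,Phrynobatrachus bequaerti,0.1422
malalo,Hyperolius castaneus,Hyperolius glandicolor,0.3339
malalo,Hyperolius castaneus,Leptopelis karissimbensis,0.4678
malalo,Hyperolius castaneus,Leptopelis kivuensis,0.5766
malalo,Hyperolius castaneus,Phrynobatrachus bequaerti,0.4402
malalo,Hyperolius glandicolor,Leptopelis karissimbensis,0.2190
malalo,Hyperolius glandicolor,Leptopelis kivuensis,0.2565
malalo,Hyperolius glandicolor,Phrynobatrachus bequaerti,0.3455
malalo,Leptopelis karissimbensis,Leptopelis kivuensis,0.6898
malalo,Leptopelis karissimbensis,Phrynobatrachus bequaerti,0.4275
malalo,Leptopelis kivuensis,Phrynobatrachus bequaerti,0.4185
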