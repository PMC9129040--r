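species_id,B_s,A_s,E_s
B_caeruleus,2.5e-05,0.80,0.95
B_ceylonicus,3.5e-05,0.70,0.85
D_russelii,1.0e-05,0.60,0.90
E_carinatus,2.0e-05,0.65,0.80
Hypnale_spp,3.0e-06,0.40,0.35
N_naja,5.0e-05,0.90,0.90
T_trigonocephalus,5.0e-06,0.30,0.25
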