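(((((((Amphiprion_ocellaris:0.05,Amphiprion_percula:0.05):0.08,(Amphiprion_akallopisos:0.06,(Amphiprion_nigripes:0.04,Amphiprion_perideraion:0.04):0.02):0.07):0.03,((Amphiprion_bicinctus:0.07,Amphiprion_clarkii:0.07):0.04,((Amphiprion_frenatus:0.05,Amphiprion_melanopus:0.05):0.03,(Amphiprion_polymnus:0.06,Amphiprion_sebae:0.06):0.02):0.03):0.05):0.08,Premnas_biaculeatus:0.24):0.16,Pomacentrus_moluccensis:0.4):0.1,(Acanthochromis_polyacanthus:0.35,Chromis_chromis:0.35):0.15):0.5,Stegastes_partitus:1.0);
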