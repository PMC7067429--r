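>SCG2B_short species=Amphiprion_percula type=G region=EM66-like
TEESDAKAAQGI
>SCG2B_long species=Amphiprion_ocellaris type=T region=EM66-like
TEESESAKAAQGI
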