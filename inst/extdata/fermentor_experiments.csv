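id,strains,substrate,loading_g_l,ph_mode,substrate_final_g_l,ethanol_mM,acetate_mM,lactate_mM,co2_mM,h2_mM,cdw_g_l,replicate
f-01,DIB004C,avicel,20,ph-controlled-fermentor,,29.9,32.9,20.9,,,,1
f-02,DIB004C+DIB004G,avicel,20,ph-controlled-fermentor,,72.5,36.3,43.5,,,,1
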