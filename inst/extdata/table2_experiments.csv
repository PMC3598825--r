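id,strains,substrate,loading_g_l,ph_mode,substrate_final_g_l,ethanol_mM,acetate_mM,lactate_mM,co2_mM,h2_mM,cdw_g_l,replicate
t2-01,DIB004C,avicel,10,uncontrolled-flask,,2.7,21.4,9.0,,,,1
t2-02,DIB004C+DIB004G,avicel,10,uncontrolled-flask,,8.8,19.9,11.0,,,,1
t2-03,DIB004C+DIB097X,avicel,10,uncontrolled-flask,,10.3,18.6,11.8,,,,1
t2-04,DIB004C,washed_poplar,2.9,uncontrolled-flask,,1.5,10.9,6.2,,,,1
t2-05,DIB004C+DIB004G,washed_poplar,2.9,uncontrolled-flask,,5.7,14.0,6.6,,,,1
t2-06,DIB004C+DIB097X,washed_poplar,2.9,uncontrolled-flask,,3.7,14.1,8.3,,,,1
t2-07,DIB004C,unwashed_poplar,10,uncontrolled-flask,,2.6,12.0,6.1,,,,1
t2-08,DIB004G,unwashed_poplar,10,uncontrolled-flask,,4.3,4.4,3.0,,,,1
t2-09,DIB097X,unwashed_poplar,10,uncontrolled-flask,,5.1,4.3,0.0,,,,1
t2-10,DIB004C+DIB004G,unwashed_poplar,10,uncontrolled-flask,,5.7,11.6,3.1,,,,1
t2-11,DIB004C+DIB097X,unwashed_poplar,10,uncontrolled-flask,,7.0,11.4,3.5,,,,1
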