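id,strains,substrate,loading_g_l,ph_mode,substrate_final_g_l,ethanol_mM,acetate_mM,lactate_mM,co2_mM,h2_mM,cdw_g_l,replicate
t3-01,DIB004C,glucose,10,uncontrolled-flask,4.487,5.5,21.9,35.3,8.8,20.8,0.25,1
t3-02,DIB097X,glucose,10,uncontrolled-flask,0.019,53.1,5.3,55.6,9.5,2.4,0.37,1
t3-03,DIB004C,avicel,10,uncontrolled-flask,5.88,4.8,11.6,30.4,9.1,10.0,0.24,1
t3-04,DIB004C+DIB097X,avicel,10,uncontrolled-flask,6.34,6.2,10.3,25.7,12.6,9.2,0.19,1
t3-05,DIB004C,washed_poplar,6.05,uncontrolled-flask,4.80,0.2,13.3,7.5,5.1,8.1,0.30,1
t3-06,DIB004C+DIB097X,washed_poplar,6.05,uncontrolled-flask,4.21,3.2,13.2,6.3,5.7,11.0,0.26,1
t3-07,DIB004C,washed_miscanthus,6.09,uncontrolled-flask,4.14,2.7,11.6,6.3,4.4,7.2,0.23,1
t3-08,DIB004C+DIB097X,washed_miscanthus,6.09,uncontrolled-flask,4.08,5.2,13.0,5.5,4.0,9.8,0.22,1
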