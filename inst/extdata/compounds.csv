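name,carbon,hydrogen,oxygen,nitrogen,molar_mass
glucose,6,12,6,0,180.16
galactose,6,12,6,0,180.16
mannose,6,12,6,0,180.16
xylose,5,10,5,0,150.13
arabinose,5,10,5,0,150.13
anhydrohexose,6,10,5,0,162.14
anhydropentose,5,8,4,0,132.11
ethanol,2,6,1,0,46.07
acetate,2,4,2,0,60.05
lactate,3,6,3,0,90.08
co2,1,0,2,0,44.01
h2,0,2,0,0,2.016
water,0,2,1,0,18.02
biomass,1,2,0.5,0.25,25.53
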