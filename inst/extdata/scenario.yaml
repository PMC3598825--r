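# Default simulation scenario: a lactogenic cellulolytic strain alone and
# in co-culture with an ethanologenic saccharolytic partner on 10 g/l
# microcrystalline cellulose in unbuffered flasks. Product splits are the
# organic-product mole fractions typical of such pairings.
strains:
  - name: cellu
    product_split: [0.082, 0.646, 0.272]
    biomass_fraction: 0.05
    consumption_extent: 0.90
    scope: cellulolytic
  - name: thermo
    product_split: [0.683, 0.061, 0.256]
    biomass_fraction: 0.05
    consumption_extent: 0.95
    scope: saccharolytic
substrate:
  name: avicel
  composition:
    glucan: 1.0
  loading_g_l: 10
cultures:
  - [cellu]
  - [cellu, thermo]
replicates: 3
noise_relative_sd: 0.05
ph_mode: uncontrolled-flask
share: 0.5
acid_threshold: 30
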