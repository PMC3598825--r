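substrate,polymer,fraction
washed_poplar,glucan,0.581
washed_poplar,xylan,0.001
washed_poplar,galactan,0.002
washed_poplar,lignin_acid_soluble,0.027
washed_poplar,lignin_acid_insoluble,0.348
washed_poplar,ash,0.001
raw_poplar,glucan,0.424
raw_poplar,xylan,0.116
raw_poplar,galactan,0.018
raw_poplar,arabinan,0.022
raw_poplar,mannan,0.026
raw_poplar,lignin_acid_soluble,0.054
raw_poplar,lignin_acid_insoluble,0.250
raw_poplar,ash,0.005
avicel,glucan,1.0
washed_miscanthus,glucan,0.580
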