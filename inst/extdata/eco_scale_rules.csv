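category,bracket,points
reagent-amount,<10 mL or g,1
reagent-amount,10-100 mL or g,2
reagent-amount,>100 mL or g,3
reagent-hazard,none,0
reagent-hazard,per pictogram with signal word warning,1
reagent-hazard,per pictogram with signal word danger,2
instrument-energy,<=0.1 kWh per sample,0
instrument-energy,<=1.5 kWh per sample,1
instrument-energy,>1.5 kWh per sample,2
occupational-hazard,hermetic process,0
occupational-hazard,emission of vapours and gases to the air,3
waste,none,0
waste,<1 mL or g,1
waste,1-10 mL or g,3
waste,>10 mL or g,5
waste-treatment,recycling,0
waste-treatment,degradation,1
waste-treatment,passivation,2
waste-treatment,no treatment,3
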