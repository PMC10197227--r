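trait,pst_mean,pst_lo,pst_hi,diff_mean,diff_lo,diff_hi
days_to_bolting,0.001,0.00,0.01,-0.02,-0.02,-0.01
days_to_first_flower,0.002,0.00,0.01,-0.02,-0.02,-0.009
final_plant_height,0.007,0.00,0.03,-0.02,-0.02,0.007
capitula_number,0.25,0.18,0.32,0.23,0.16,0.30
seed_mass,0.19,0.08,0.30,0.16,0.05,0.27
length_of_largest_spine,0.002,0.00,0.01,-0.02,-0.02,-0.01
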