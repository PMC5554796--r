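group,scenario,n_countries,mean_population_end_term_millions,mean_annual_cost_end_term_billions
all_countries,ambitious,67,6286,371
low_income,ambitious,28,804,66
lower_middle_income,ambitious,21,3127,183
upper_middle_income,ambitious,18,2355,119
conflict,ambitious,4,110,10
vulnerable,ambitious,11,334,33
hs1,ambitious,16,471,34
hs2,ambitious,16,2800,163
hs3,ambitious,21,2571,127
all_countries,progress,67,6402,274
low_income,progress,28,708,52
lower_middle_income,progress,21,3402,141
upper_middle_income,progress,18,2291,82
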