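cause,progress_averted,ambitious_averted
stillbirths,6700000,11400000
neonatal,13800000,19400000
post_neonatal,15400000,21500000
maternal,1500000,2100000
cancer,2900000,4300000
cvd_diabetes_depression_epilepsy,11650000,16130000
tuberculosis,11200000,11200000
hiv_aids,8100000,10800000
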