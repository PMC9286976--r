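tube_id: 1
fly_id: ctrl_A
genotype: control
age_days: 20
dose_ug_per_ml: 0

tube_id: 2
fly_id: park_B
genotype: park25
age_days: 20
dose_ug_per_ml: 9
start_day: 0
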