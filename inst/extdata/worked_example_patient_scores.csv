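feature,value_low,score_low,value_high,score_high
age,42.77,49.02,71.07,51.82
sex_male,1,48.52,1,48.52
height,160.4,49.78,156.3,49.91
weight,61.8,48.60,55.8,53.02
bmi,24.02,48.85,22.84,48.85
asa,1,46.17,4,53.76
emergency,0,47.10,1,52.95
hypertension,0,49.30,0,49.30
diabetes,0,49.83,0,49.83
prior_cva,0,47.39,0,47.39
asthma,0,50.00,0,50.00
copd,0,49.59,0,49.59
liver_disease,0,49.81,1,50.17
kidney_disease,0,49.80,0,49.80
tuberculosis,0,49.80,0,49.80
highrisk_surgery,0,0,1,100
hemoglobin,13,49.66,12,49.49
platelet,293,49.80,92,50.66
bun,14,49.27,8,49.27
creatinine,0,50.40,0,50.40
albumin,4,50.54,3,55.35
sodium,137,50.41,137,50.41
potassium,4,53.46,3,50.75
glucose,81,47.39,115,54.08
pt,11.9,52.13,11.6,52.13
ptt,28,46.54,28,46.54
ast,14,47.30,64,52.37
alt,22,49.64,78,50.30
egfr,120,49.06,90,50.83
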