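quantity,count,total
female,1121,3307
male,2186,3307
readmitted_14d,423,3307
readmitted_30d,879,3307
tbil_above_normal_admission_14d,304,423
tbil_above_normal_admission_30d,531,879
tbil_above_normal_discharge_14d,279,423
tbil_above_normal_discharge_30d,481,879
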