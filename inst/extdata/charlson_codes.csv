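category,icd9_prefix
myocardial_infarction,410
heart_failure,428
copd,496
diabetes,250
renal_disease,585
liver_disease,571
cancer,153
cancer,162
cancer,174
cerebrovascular,434
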