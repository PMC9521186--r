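condition,icd9_prefix
hypertension,401
hypertension,402
hypertension,403
hypertension,404
hypertension,405
diabetes,250
cancer,153
cancer,162
cancer,174
thyroid_disease,244
lipid_disorders,272
depression,311
infections,038
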