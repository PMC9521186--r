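outcome,icd9_prefix
reject,996.8
infection,038
diabetes,250
cancer,199
cancer,162
cancer,155
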