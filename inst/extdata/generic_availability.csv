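agent,first_generic_date
CsA,2009-01-01
AZA,2009-01-01
MMF,2011-01-01
TAC,2014-01-01
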