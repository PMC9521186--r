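class,atc_prefix
anticoagulants,B01AA
anticoagulants,B01AB
antiplatelet,B01AC
statins,C10AA
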