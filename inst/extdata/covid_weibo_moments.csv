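variable,mean,sd,min
epidemic_severity,1929.68,2325.36,77
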