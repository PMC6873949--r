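type,time,fraction
nonevolving,10,0.10
nonevolving,20,0.13
evolving,10,0.55
evolving,20,0.80
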