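((t1:0.1,t2:0.1):0.1,t3:0.1,t4:0.1);
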