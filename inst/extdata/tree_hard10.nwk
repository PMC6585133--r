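(((t1:0.15,t2:0.2):0.03,(t3:0.25,t4:0.1):0.03):0.03,((t5:0.2,t6:0.12):0.03,(t7:0.3,t8:0.15):0.03):0.03,(t9:0.25,t10:0.1):0.03);
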