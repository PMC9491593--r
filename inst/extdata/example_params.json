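{"f":0.15,"U":0.25,"F_s":0.25,"D_s":0.25,"A":1,"tau_syn_s":0.003}
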