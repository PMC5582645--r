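state,well,ill,dead
well,-2,1,1
ill,0,-1,1
dead,0,0,0
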