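wgd,poor,predicted,high
None,71,119,2
One,3,39,5
MoreThanTwo,1,3,5
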