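feed,ap,ndf,tnc1,tnc_anchor
Beta vulgaris,4.5,12.0,65.0,yes
Solanum tuberosum,6.0,6.0,74.0,yes
Daucus carota,5.5,10.0,60.0,yes
Pisum sativum,19.0,14.0,50.0,no
Grass silage,11.0,50.0,14.0,no
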