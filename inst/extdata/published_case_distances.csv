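pair,distance
philips_vs_hamamatsu,0.0040
philips_vs_3dhistech,0.0074
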