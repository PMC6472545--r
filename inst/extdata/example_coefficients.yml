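# Example coefficient overrides: AR5 100-yr GWP factors and a shorter
# middle-rice cycle. Unlisted keys keep the packaged calibrated defaults.
gwp_ch4: 28
gwp_n2o: 265
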