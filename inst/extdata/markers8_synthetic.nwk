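((marker01:0.02,marker02:0.03):0.05,((marker03:0.04,marker04:0.04):0.03,((marker05:0.05,marker06:0.06):0.02,(marker07:0.07,marker08:0.08):0.03):0.02):0.04);
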