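name	module_start	module_end
MXAN_7418	24	415
MXAN_3226	23	381
MXAN_1916	26	421
PgaA_bb	511	807
GfcD_Cterbb	425	698
YjbH_Cterbb	423	698
BcsC_bb	785	1157
AlgE	33	490
Wzi_bb	92	479
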