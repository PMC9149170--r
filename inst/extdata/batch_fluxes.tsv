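reaction	value	units
Upt	0.4753	mol/Cmol_X/h
UGlc	0.4373	mol/Cmol_X/h
LGlc	0.8745	mol/Cmol_X/h
Ferm	0.7272	mol/Cmol_X/h
Esnk	0.0428	mol/Cmol_X/h
Resp	0.0808	mol/Cmol_X/h
TrSn	0.0051	mol/Cmol_X/h
TrDg	0.0041	mol/Cmol_X/h
Grwt	0.4	1/h
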