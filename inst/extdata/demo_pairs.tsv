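CCL2	CCR5
CCL3	CCR5
CCL8	CCR5
CYR61	ITGAM
CYR61	ITGA5
CYR61	CAV1
ANGPT1	TEK
CCL21	CCBP2
L1CAM	CNTN1
NCAM1	GFRA1
MDK	GPC2
CTGF	LRP1
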