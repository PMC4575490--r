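gene	sample	replicate	ct
ACTN1	AG1BM16	1	25.22
ACTN1	AG1BM16	2	25.17
ACTN1	AG1BM16	3	25.34
ACTN1	AG1BM4	1	25.12
ACTN1	AG1BM4	2	25.09
ACTN1	AG1BM4	3	25.02
ACTN1	AG1BM64	1	25.19
ACTN1	AG1BM64	2	25.18
ACTN1	AG1BM64	3	24.87
ACTN1	AGO	1	25.11
ACTN1	AGO	2	24.9
ACTN1	AGO	3	24.87
ACTN1	BMO	1	25.04
ACTN1	BMO	2	25.21
ACTN1	BMO	3	25.15
GUSB	AG1BM16	1	22.28
GUSB	AG1BM16	2	22.14
GUSB	AG1BM16	3	21.88
GUSB	AG1BM4	1	21.98
GUSB	AG1BM4	2	21.96
GUSB	AG1BM4	3	21.92
GUSB	AG1BM64	1	22.11
GUSB	AG1BM64	2	21.76
GUSB	AG1BM64	3	21.9
GUSB	AGO	1	22.34
GUSB	AGO	2	21.92
GUSB	AGO	3	22.06
GUSB	BMO	1	21.85
GUSB	BMO	2	22.11
GUSB	BMO	3	21.93
HES1	AG1BM16	1	24.26
HES1	AG1BM16	2	24.15
HES1	AG1BM16	3	24.14
HES1	AG1BM4	1	24.77
HES1	AG1BM4	2	24.55
HES1	AG1BM4	3	24.74
HES1	AG1BM64	1	24.24
HES1	AG1BM64	2	24.09
HES1	AG1BM64	3	24.14
HES1	AGO	1	26.82
HES1	AGO	2	27.15
HES1	AGO	3	26.86
HES1	BMO	1	23.96
HES1	BMO	2	24.05
HES1	BMO	3	23.98
IGFBP4	AG1BM16	1	27.21
IGFBP4	AG1BM16	2	27.34
IGFBP4	AG1BM16	3	27.29
IGFBP4	AG1BM4	1	27.2
IGFBP4	AG1BM4	2	26.82
IGFBP4	AG1BM4	3	27.24
IGFBP4	AG1BM64	1	27.25
IGFBP4	AG1BM64	2	27.49
IGFBP4	AG1BM64	3	27.5
IGFBP4	AGO	1	24.9
IGFBP4	AGO	2	24.83
IGFBP4	AGO	3	24.91
IGFBP4	BMO	1	27.37
IGFBP4	BMO	2	27.67
IGFBP4	BMO	3	27.58
LAMB1	AG1BM16	1	24.55
LAMB1	AG1BM16	2	24.65
LAMB1	AG1BM16	3	24.55
LAMB1	AG1BM4	1	24.93
LAMB1	AG1BM4	2	24.81
LAMB1	AG1BM4	3	24.93
LAMB1	AG1BM64	1	24.71
LAMB1	AG1BM64	2	24.39
LAMB1	AG1BM64	3	24.65
LAMB1	AGO	1	25.94
LAMB1	AGO	2	25.98
LAMB1	AGO	3	25.87
LAMB1	BMO	1	24.61
LAMB1	BMO	2	24.62
LAMB1	BMO	3	24.59
TFRC	AG1BM16	1	24.75
TFRC	AG1BM16	2	25.01
TFRC	AG1BM16	3	24.48
TFRC	AG1BM4	1	25.01
TFRC	AG1BM4	2	24.8
TFRC	AG1BM4	3	24.6
TFRC	AG1BM64	1	24.82
TFRC	AG1BM64	2	24.8
TFRC	AG1BM64	3	24.7
TFRC	AGO	1	23.85
TFRC	AGO	2	24.05
TFRC	AGO	3	23.75
TFRC	BMO	1	24.82
TFRC	BMO	2	24.97
TFRC	BMO	3	24.79
VIM	AG1BM16	1	22.77
VIM	AG1BM16	2	22.73
VIM	AG1BM16	3	22.71
VIM	AG1BM4	1	23.04
VIM	AG1BM4	2	22.79
VIM	AG1BM4	3	22.7
VIM	AG1BM64	1	22.72
VIM	AG1BM64	2	22.63
VIM	AG1BM64	3	22.77
VIM	AGO	1	22.86
VIM	AGO	2	23.18
VIM	AGO	3	22.8
VIM	BMO	1	22.59
VIM	BMO	2	22.79
VIM	BMO	3	22.42
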