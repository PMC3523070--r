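pathway	neglogp_sjia_esr	neglogp_sjia_jc	reported_difference	direction_with_higher_covariate
Glucocorticoid receptor signaling	5.68	3.07	2.61	higher
PI3K/AKT signaling	1.27	3.73	-2.45	higher
Role of PKR in interferon induction and antiviral response	4.43	4.43	0	higher
Altered T cell and B cell signaling in rheumatoid arthritis	3.91	3.91	0	higher
T helper cell differentiation	3.74	3.74	0	lower
iCOS-iCOSL signaling in T helper cells	3.73	3.73	0	lower
CD40 signaling	3.73	3.73	0	lower
MIF regulation of innate immunity	3.70	3.70	0	higher
LPS-stimulated MAPK signaling	3.42	3.42	0	higher
CD27 signaling in lymphocytes	3.18	3.18	0	higher
MIF-mediated glucocorticoid regulation	3.02	3.02	0	higher
Role of cytokines in mediating communication between immune cells	3.01	3.01	0	higher
TREM1 signaling	2.91	2.91	0	higher
Crosstalk between dendritic cells and natural killer cells	2.81	2.81	0	lower
Docosahexaenoic acid (DHA) signaling	2.76	2.76	0	higher
Regulation of IL-2 expression in activated and anergic T lymphocytes	2.39	2.39	0	higher
Toll-like receptor signaling	2.37	2.37	0	lower
fMLP signaling in neutrophils	2.33	2.33	0	higher
TNFR1 signaling	2.22	2.22	0	higher
RANK signaling in osteoclasts	2.16	2.16	0	lower
4-1BB signaling in T lymphocytes	2.12	2.12	0	higher
CD28 signaling in T helper cells	2.11	2.11	0	lower
Communication between innate and adaptive immune cells	2.06	2.06	0	higher
T cell receptor signaling	2.03	2.03	0	lower
ILK signaling	2.01	2.01	0	higher
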