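pathway	neglogp_sjia_esr	neglogp_poly_esr	reported_difference	direction_with_higher_covariate
IL-10 signaling	8.56	4.22	4.34	higher
Role of macrophages, fibroblasts and endothelial cells in rheumatoid arthritis	6.80	1.14	5.65	higher
Role of osteoblasts, osteoclasts and chondrocytes in rheumatoid arthritis	5.84	0.82	5.01	higher
Glucocorticoid receptor signaling	5.68	1.34	4.34	higher
B cell receptor signaling	5.60	2.07	3.53	higher
Role of PKR in interferon induction and antiviral response	4.43	0.86	3.56	higher
Systemic lupus Erythematosus signaling	4.08	0.46	3.62	higher
Altered T cell and B cell signaling in rheumatoid arthritis	3.91	1.34	2.57	higher
A proliferation-inducing ligand mediated signaling	3.80	0.95	2.86	lower
IL-15 signaling	3.76	0.76	3.01	lower
T helper cell differentiation	3.74	0.00	3.74	lower
iCOS-iCOSL signaling in T helper cells	3.73	0.51	3.22	lower
CD40 signaling	3.73	0.75	2.98	lower
B cell activating factor signaling	3.70	0.93	2.77	lower
Dendritic cell maturation	3.65	0.94	2.71	higher
IL-12 signaling and production in macrophages	3.08	0.52	2.55	lower
p38 MAPK signaling	3.08	0.52	2.55	higher
PPAR alpha/RXR alpha activation	2.96	0.42	2.55	higher
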