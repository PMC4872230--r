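pair	AU	UA	CG	GC	GU	UG
AU	-0.93	-1.10	-2.24	-2.08	-1.36	-0.55
UA	-1.33	-0.93	-2.35	-2.11	-1.27	-1.00
CG	-2.11	-2.08	-3.26	-2.36	-2.11	-1.41
GC	-2.35	-2.24	-3.42	-3.26	-2.51	-1.53
GU	-1.27	-1.36	-2.51	-2.11	-0.50	1.30
UG	-0.55	-0.55	-1.53	-1.41	0.30	-0.50
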