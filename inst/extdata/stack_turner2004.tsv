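pair1	pair2	kcal_per_mol
CG	CG	-2.4
CG	GC	-3.3
GC	GC	-3.4
CG	GU	-2.1
GC	GU	-2.5
GU	GU	1.3
CG	UG	-1.4
GC	UG	-1.5
GU	UG	-0.5
UG	UG	0.3
CG	AU	-2.1
GC	AU	-2.2
GU	AU	-1.4
UG	AU	-0.6
AU	AU	-1.1
CG	UA	-2.1
GC	UA	-2.4
GU	UA	-1.3
UG	UA	-1
AU	UA	-0.9
UA	UA	-1.3
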