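modres	parent
MSE	MET
SEC	CYS
PYL	LYS
HYP	PRO
SEP	SER
TPO	THR
PTR	TYR
MLY	LYS
M3L	LYS
CSO	CYS
KCX	LYS
CME	CYS
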