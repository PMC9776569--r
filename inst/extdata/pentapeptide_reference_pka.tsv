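type	pka
Asp	3.94
Glu	4.25
His	6.54
Cys	8.55
Tyr	9.84
Lys	10.40
NTr	8.00
CTr	3.67
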