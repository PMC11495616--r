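PVC	AVA
AVA	PVC
AVA	AVB
AVB	AVA
AVA	VA08
AVB	VB06
PVC	VA08
VA08	VB06
VB06	VA08
DVA	PVC
DVA	AVA
DVA	AVB
VA08	DA02
VB06	DA02
DA02	AVA
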