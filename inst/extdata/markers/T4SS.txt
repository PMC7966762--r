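# Type IV secretion system components (conjugative transfer)
virB1
virB2
virB3
virB4
virB5
virB6
virB7
virB8
virB9
virB10
virB11
virD4
traG
trbE
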