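# AHBA high-risk Alzheimer's disease gene panel (28 symbols)
A2M
ACE
ACHE
APBA1
APBB2
APLP1
APLP2
APOC1
APP
BACE2
BCHE
BLMH
CASP3
CHRNA3
CTSB
DBN1
ESR1
GSK3B
IL1B
KCNIP3
KLK6
LRP1
LRRC15
MAPT
PLAU
PSEN1
PSEN2
SORL1
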