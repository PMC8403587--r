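domain	length	description
SAT	240	synthetic reference segment
KS	300	synthetic reference segment
AT	250	synthetic reference segment
PT	220	synthetic reference segment
ACP	80	synthetic reference segment
CMeT	200	synthetic reference segment
DH	180	synthetic reference segment
ER	250	synthetic reference segment
KR	220	synthetic reference segment
TE	200	synthetic reference segment
R	250	synthetic reference segment
C	300	synthetic reference segment
A	400	synthetic reference segment
T	80	synthetic reference segment
E	250	synthetic reference segment
GGPPS	250	synthetic reference segment
TC	250	synthetic reference segment
CS	300	synthetic reference segment
FAS_alpha	500	synthetic reference segment
FAS_beta	450	synthetic reference segment
PTase	250	synthetic reference segment
LSS	400	synthetic reference segment
SHC	400	synthetic reference segment
DMAT	300	synthetic reference segment
GT	250	synthetic reference segment
CDPS	200	synthetic reference segment
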