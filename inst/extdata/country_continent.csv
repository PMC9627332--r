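country,continent
US,NorthAmerica
CA,NorthAmerica
MX,NorthAmerica
BR,SouthAmerica
AR,SouthAmerica
CO,SouthAmerica
PE,SouthAmerica
CL,SouthAmerica
GB,Europe
DE,Europe
FR,Europe
IT,Europe
ES,Europe
NL,Europe
SE,Europe
CH,Europe
AT,Europe
PL,Europe
DK,Europe
NO,Europe
JP,Asia
CN,Asia
KR,Asia
IN,Asia
TW,Asia
IL,Asia
TH,Asia
ZA,Africa
NG,Africa
EG,Africa
TN,Africa
MA,Africa
AU,Oceania
NZ,Oceania
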