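*NEWRECORD
RECTYPE = D
MH = Humans
AQ = AH GE IM PH
MN = B01.050.150.900.649.801.400.112.400.400
MS = Members of the species Homo sapiens.

*NEWRECORD
RECTYPE = D
MH = Mice
MN = B01.050.150.900.649.313.992.635.505.500
MS = The common house mouse, Mus musculus.

*NEWRECORD
RECTYPE = D
MH = Neoplasms
MN = C04
MS = New abnormal growth of tissue.

*NEWRECORD
RECTYPE = D
MH = Tumor Cells, Cultured
MN = A11.251.860.900
MN = C04.557.337
MS = Cells grown in vitro from neoplastic tissue.

*NEWRECORD
RECTYPE = D
MH = Female
MS = A check tag with no tree address.
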