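CCO ethanol
CCCO propanol
CC(C)O isopropanol
CCN ethylamine
CCOCC diethyl_ether
CC(=O)O acetic_acid
CC(=O)OC methyl_acetate
c1ccccc1 benzene
c1ccccc1O phenol
c1ccccc1N aniline
Cc1ccccc1 toluene
c1ccc2ccccc2c1 naphthalene
C1CCCCC1 cyclohexane
C1CCOCC1 oxane
C1CCNCC1 piperidine
CC(C)CC(C)O methylpentanol
OCC1OC(O)C(O)C(O)C1O glucose
COC1OC(CO)C(O)C(O)C1O methyl_glucoside
CC1CCC(C(C)C)CC1 menthane
CCC(=O)CC(O)CC(=O)O polyketide_frag
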