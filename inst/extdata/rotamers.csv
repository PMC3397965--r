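# Coarse side-chain rotamer library: common gauche-/gauche+/trans chi-angle
# combinations per residue type (degrees, in (-180, 180]). A compact,
# package-authored set in the spirit of curated rotamer libraries; edit or
# replace via the rotamers argument of the optimizer.
resid,chi1,chi2
SER,-60,NA
SER,60,NA
SER,180,NA
THR,-60,NA
THR,60,NA
THR,180,NA
CYS,-60,NA
CYS,60,NA
CYS,180,NA
VAL,-60,NA
VAL,180,NA
VAL,60,NA
LEU,-60,180
LEU,180,60
ILE,-60,170
ILE,-60,-60
ILE,180,170
MET,-60,180
MET,180,180
MET,-60,-60
PHE,-60,90
PHE,180,80
TYR,-60,90
TYR,180,80
TRP,-60,95
TRP,180,-105
HIS,-60,-75
HIS,180,60
LYS,-60,180
LYS,180,180
ARG,-60,180
ARG,180,180
ASP,-60,-15
ASP,180,15
ASN,-60,-20
ASN,180,30
GLU,-60,180
GLU,180,180
GLN,-60,180
GLN,180,180
SEP,-60,NA
SEP,60,NA
SEP,180,NA
ALA,0,NA
TOY,-60,NA
TOY,60,NA
TOY,180,NA
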