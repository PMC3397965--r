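# Hydrogen-bond class dictionary: donor / acceptor / both / nonpolar.
# resid "*" matches any residue (backbone and generic names); exact
# (resid, name) entries take precedence. Editable: unknown atoms fall back
# to element rules (N donor, O acceptor, else nonpolar) with a warning.
resid,name,class
*,N,donor
*,CA,nonpolar
*,C,nonpolar
*,O,acceptor
*,OXT,acceptor
*,CB,nonpolar
PRO,N,nonpolar
SER,OG,both
THR,OG1,both
TYR,OH,both
CYS,SG,both
LYS,NZ,donor
ARG,NE,donor
ARG,NH1,donor
ARG,NH2,donor
ARG,CZ,nonpolar
ASP,OD1,acceptor
ASP,OD2,acceptor
GLU,OE1,acceptor
GLU,OE2,acceptor
ASN,OD1,acceptor
ASN,ND2,donor
GLN,OE1,acceptor
GLN,NE2,donor
HIS,ND1,both
HIS,NE2,both
TRP,NE1,donor
MET,SD,nonpolar
SEP,OG,acceptor
SEP,P,nonpolar
SEP,O1P,acceptor
SEP,O2P,acceptor
SEP,O3P,acceptor
SEP,OT,acceptor
ACE,CH3,nonpolar
ACE,C,nonpolar
ACE,O,acceptor
HOH,O,both
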