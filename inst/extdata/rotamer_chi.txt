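# Backbone-independent side-chain rotamer modes.
# Format: AA chi1 [chi2 [chi3 [chi4]]] weight   (angles in degrees)
# One row per rotamer; rows are ordered by decreasing weight within each
# amino acid and the first row is the library's seed rotamer. The chi values
# are the classic staggered (+/-60, 180) modes, with +/-90 for aromatic
# chi2, and the weights are canonical mode frequencies rounded to two
# figures. A user-supplied table in the same format may be passed to
# load_rotamer_library() instead.
ALA 1.00
GLY 1.00
PRO 27 -35 1.00
SER -60 0.48
SER 60 0.29
SER 180 0.23
CYS -60 0.52
CYS 180 0.26
CYS 60 0.22
THR 60 0.49
THR -60 0.43
THR 180 0.08
VAL 180 0.73
VAL -60 0.20
VAL 60 0.07
LEU -60 180 0.55
LEU 180 60 0.30
LEU -60 60 0.08
LEU 180 180 0.07
ILE -60 180 0.60
ILE -60 -60 0.15
ILE 180 180 0.15
ILE 60 180 0.10
MET -60 180 180 0.35
MET -60 180 -60 0.25
MET 180 180 180 0.25
MET 180 60 60 0.15
PHE -60 90 0.45
PHE 180 90 0.35
PHE 60 90 0.20
TYR -60 90 0.45
TYR 180 90 0.35
TYR 60 90 0.20
TRP -60 -90 0.30
TRP -60 90 0.20
TRP 180 -90 0.20
TRP 180 90 0.15
TRP 60 -90 0.10
TRP 60 90 0.05
ASP -60 -60 0.25
ASP -60 60 0.20
ASP 180 60 0.20
ASP 180 -60 0.15
ASP 60 -60 0.10
ASP 60 60 0.10
ASN -60 -60 0.25
ASN -60 60 0.20
ASN 180 60 0.20
ASN 180 -60 0.15
ASN 60 -60 0.10
ASN 60 60 0.10
HIS -60 -60 0.25
HIS -60 60 0.20
HIS 180 60 0.20
HIS 180 -60 0.15
HIS 60 -60 0.10
HIS 60 60 0.10
GLU -60 180 -60 0.22
GLU -60 180 60 0.16
GLU 180 180 -60 0.14
GLU 180 180 60 0.12
GLU -60 -60 -60 0.10
GLU -60 -60 60 0.08
GLU 180 -60 -60 0.07
GLU 60 180 -60 0.06
GLU 60 180 60 0.05
GLN -60 180 -60 0.22
GLN -60 180 60 0.16
GLN 180 180 -60 0.14
GLN 180 180 60 0.12
GLN -60 -60 -60 0.10
GLN -60 -60 60 0.08
GLN 180 -60 -60 0.07
GLN 60 180 -60 0.06
GLN 60 180 60 0.05
LYS -60 180 180 180 0.28
LYS 180 180 180 180 0.22
LYS -60 180 180 -60 0.12
LYS -60 180 -60 180 0.10
LYS 180 180 180 60 0.08
LYS -60 -60 180 180 0.08
LYS 60 180 180 180 0.07
LYS 180 -60 180 180 0.05
ARG -60 180 180 180 0.26
ARG 180 180 180 180 0.20
ARG -60 180 -60 180 0.12
ARG -60 180 180 -60 0.10
ARG 180 180 -60 180 0.09
ARG -60 -60 180 180 0.09
ARG 60 180 180 180 0.08
ARG 180 -60 180 -60 0.06
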