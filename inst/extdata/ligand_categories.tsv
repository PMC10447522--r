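code	category
GLC	carbohydrates
BGC	carbohydrates
GAL	carbohydrates
MAN	carbohydrates
BMA	carbohydrates
FUC	carbohydrates
FUL	carbohydrates
XYS	carbohydrates
NAG	carbohydrates
NDG	carbohydrates
G7P	carbohydrates
SUC	carbohydrates
TRE	carbohydrates
MAL	carbohydrates
LAT	carbohydrates
NAD	nucleotides
NAI	nucleotides
NAP	nucleotides
NDP	nucleotides
FAD	nucleotides
FMN	nucleotides
ATP	nucleotides
ADP	nucleotides
AMP	nucleotides
ANP	nucleotides
GTP	nucleotides
GDP	nucleotides
GMP	nucleotides
UMP	nucleotides
TMP	nucleotides
CMP	nucleotides
CIT	acids_anions
FLC	acids_anions
MLI	acids_anions
MLA	acids_anions
ACT	acids_anions
FMT	acids_anions
AKG	acids_anions
OAA	acids_anions
PLM	acids_anions
MYR	acids_anions
OLA	acids_anions
STE	acids_anions
TAR	acids_anions
MLT	acids_anions
HEM	hemes
HEC	hemes
HEA	hemes
HEB	hemes
DHE	hemes
SRM	hemes
VER	hemes
SAH	nonproteinogenic_amino_acids
SAM	nonproteinogenic_amino_acids
DGL	nonproteinogenic_amino_acids
DAL	nonproteinogenic_amino_acids
DSN	nonproteinogenic_amino_acids
CSO	nonproteinogenic_amino_acids
MSE	nonproteinogenic_amino_acids
ORN	nonproteinogenic_amino_acids
CIR	nonproteinogenic_amino_acids
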