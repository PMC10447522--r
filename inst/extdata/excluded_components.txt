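# Ligand components excluded from hydrogen-bond analysis.
# One chemical-component code per line; '#' starts a comment.
# Waters
HOH
DOD
WAT
H2O
# Polyols and PEG-like cryoprotectants / precipitants
GOL   # glycerol
EDO   # ethylene glycol
PEG   # di(hydroxyethyl)ether
PG4   # tetraethylene glycol
PGE   # triethylene glycol
P6G   # hexaethylene glycol
1PE   # pentaethylene glycol
MPD   # 2-methyl-2,4-pentanediol
MRD   # (4R)-2-methylpentane-2,4-diol
BU3   # (R,R)-2,3-butanediol
PDO   # 1,3-propanediol
XYL   # xylitol
SBT   # 2-butanol
ERY   # erythritol
DMS   # dimethyl sulfoxide
BTB   # bis-tris buffer
TRS   # tris buffer
MES   # MES buffer
EPE   # HEPES buffer
# Inorganic anions
SO4   # sulfate ion
PO4   # phosphate ion
SO3   # sulfite ion
NO3   # nitrate ion
CO3   # carbonate ion
CL    # chloride
BR    # bromide
IOD   # iodide
F     # fluoride
AZI   # azide
SCN   # thiocyanate
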