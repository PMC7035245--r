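rod:
- NR2E3
- SAG
- GNAT1
- RHO
- NRL
- PDE6G
- CNGA1
- PDE6A
- ROM1
- GNGT1
ML_cone:
- ARR3
- OPN1MW
- GNAT2
- PDE6H
- GNGT2
- GUCA1C
- PDE6C
- CNGB3
S_cone:
- OPN1SW
- CCDC136
- ARR3
- GNAT2
- PDE6H
- GUCA1C
cod:
- OPN1SW
- NR2E3
- SAG
- GNAT1
- RHO
- ARR3
- GNAT2
- PDE6H
- GNGT2
developing:
- CRX
- OTX2
- RCVRN
- PRDM1
- DCT
bipolar:
- VSX1
- VSX2
- CABP5
- GRM6
- TRPM1
amacrine:
- TFAP2A
- TFAP2B
- GAD1
- SLC32A1
horizontal:
- ONECUT1
- ONECUT2
- LHX1
- CALB1
muller:
- RLBP1
- SLC1A3
- GLUL
- CLU
- APOE
RGC:
- POU4F2
- RBPMS
- NEFL
- GAP43
- SNCG
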