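name,area_nm2
MGDG,0.82
DGDG,0.64
PSII-LHCII,494
Cyt b6f,49.5
PSI,300
[subunits]
subunit,complex,stoichiometry
PsbA,PSII-LHCII,1
PetC,Cyt b6f,1
PsaC,PSI,1
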