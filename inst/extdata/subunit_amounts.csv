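analyte,analyte_class,time_h,replicate,amount
PsbA,protein_subunit,0,1,6.9E-06
PsbA,protein_subunit,4,1,9.2E-06
PsbA,protein_subunit,8,1,1.5E-05
PsbA,protein_subunit,12,1,3.2E-05
PsbA,protein_subunit,24,1,9.3E-05
PsbA,protein_subunit,48,1,2.0E-04
PsbA,protein_subunit,72,1,3.9E-04
PsbA,protein_subunit,96,1,6.2E-04
PsaC,protein_subunit,12,1,1.6E-05
PsaC,protein_subunit,24,1,7.3E-05
PsaC,protein_subunit,48,1,1.1E-04
PsaC,protein_subunit,72,1,1.7E-04
PsaC,protein_subunit,96,1,2.3E-04
PetC,protein_subunit,0,1,2.7E-05
PetC,protein_subunit,4,1,2.8E-05
PetC,protein_subunit,8,1,2.5E-05
PetC,protein_subunit,12,1,5.3E-05
PetC,protein_subunit,24,1,1.2E-04
PetC,protein_subunit,48,1,1.8E-04
PetC,protein_subunit,72,1,5.7E-04
PetC,protein_subunit,96,1,7.9E-04
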