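analyte,ion_label,exact_mz,ion_formula,backbone_positions,ionization,notes
aspartic acid 3TMS,350,350.1639,C13H32NO4Si3,1;2;3;4,APCI,[M+H]+ adduct; overlapped-by-molecular-ion [M]+ (CorMID-correctable; excluded from positional set by default)
aspartic acid 3TMS,349,349.1561,C13H31NO4Si3,1;2;3;4,both,[M]+ molecular radical ion
aspartic acid 3TMS,232,232.1189,C9H22NO2Si2,2;3;4,both,loss of carboxyl-TMS; near base peak; saturation-prone above 125 ng splitless
aspartic acid 3TMS,218,218.1033,C8H20NO2Si2,2;3,APCI,synthetic-placeholder: certified m/z and formula must be supplied by the user
aspartic acid 3TMS,188,188.0927,C7H18NOSi2,3;4,APCI,synthetic-placeholder: certified m/z and formula must be supplied by the user
aspartic acid 3TMS,190,190.0720,C6H16NO2Si2,1;2,APCI,synthetic-placeholder: certified m/z and formula must be supplied by the user
aspartic acid 2TMS,262,262.0931,C9H20NO4Si2,1;2;3;4,APCI,alternative whole-backbone fragment
aspartic acid 2TMS,245,245.0903,C9H19NO3Si2,2;3;4,APCI,synthetic-placeholder: positional assignment unverified
aspartic acid 2TMS,160,160.0794,C6H14NO2Si,2;3;4,APCI,synthetic-placeholder: positional assignment unverified
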