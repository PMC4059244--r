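# mosaicmap genotype table
# seed=NA config_hash=none
line_id,phenotype,SNP_61A,SNP_66F,SNP_69C,SNP_75F
F2_01,wild_type,MUT,MUT,MAP,MAP
F2_02,mutant,MUT,MUT,MAP,MAP
F2_03,mutant,MUT,MUT,MUT,MAP
F2_04,mutant,MUT,MUT,MUT,MAP
F2_05,wild_type,MUT,MAP,MAP,MAP
F2_06,wild_type,MUT,MAP,MAP,MAP
F2_07,wild_type,MUT,MAP,MAP,MAP
F2_08,wild_type,MUT,MAP,MAP,MAP
F2_09,wild_type,MUT,MAP,MAP,MAP
F2_10,wild_type,MUT,MAP,MAP,MAP
F2_11,wild_type,MUT,MAP,MAP,MAP
F2_12,wild_type,MUT,MAP,MAP,MAP
F2_13,wild_type,MUT,MAP,MAP,MAP
F2_14,mutant,MAP,MAP,MUT,MUT
F2_15,mutant,MAP,MUT,MUT,MUT
F2_16,mutant,MAP,MUT,MUT,MUT
F2_17,mutant,MAP,MUT,MUT,MUT
F2_18,mutant,MAP,MUT,MUT,MUT
F2_19,wild_type,MAP,MAP,MUT,MUT
F2_20,mutant,MUT,MUT,MUT,MUT
F2_21,mutant,MUT,MUT,MUT,MUT
F2_22,mutant,MUT,MUT,MUT,MUT
F2_23,mutant,MUT,MUT,MUT,MUT
F2_24,mutant,MUT,MUT,MUT,MUT
F2_25,mutant,MUT,MUT,MUT,MUT
F2_26,mutant,MUT,MUT,MUT,MUT
F2_27,mutant,MUT,MUT,MUT,MUT
F2_28,mutant,MUT,MUT,MUT,MUT
F2_29,mutant,MUT,MUT,MUT,MUT
F2_30,mutant,MUT,MUT,MUT,MUT
F2_31,mutant,MUT,MUT,MUT,MUT
F2_32,mutant,MUT,MUT,MUT,MUT
F2_33,mutant,MUT,MUT,MUT,MUT
F2_34,wild_type,MAP,MAP,MAP,MAP
F2_35,wild_type,MAP,MAP,MAP,MAP
F2_36,wild_type,MAP,MAP,MAP,MAP
F2_37,wild_type,MAP,MAP,MAP,MAP
F2_38,wild_type,MAP,MAP,MAP,MAP
F2_39,wild_type,MAP,MAP,MAP,MAP
F2_40,wild_type,MAP,MAP,MAP,MAP
F2_41,wild_type,MAP,MAP,MAP,MAP
F2_42,wild_type,MAP,MAP,MAP,MAP
F2_43,wild_type,MAP,MAP,MAP,MAP
F2_44,wild_type,MAP,MAP,MAP,MAP
F2_45,wild_type,MAP,MAP,MAP,MAP
F2_46,wild_type,MAP,MAP,MAP,MAP
F2_47,wild_type,MAP,MAP,MAP,MAP
F2_48,wild_type,MAP,MAP,MAP,MAP
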