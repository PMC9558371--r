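# Per-state ddG (kJ/mol) of KIT kinase point mutations, relative to wild type.
# Negative = mutant less stable than WT in that state.  See ?kit_printed_ddg
# for the meaning of the source and variant columns.
mutation	state	ddg_kJ_per_mol	se_kJ_per_mol	source	variant	note
V559A	inactive	-8.0	1.0	synthetic_qualitative	FALSE	JM oncogenic; destabilizing beyond threshold, numeric value synthetic
V560D	inactive	-8.0	1.0	synthetic_qualitative	FALSE	JM oncogenic; destabilizing beyond threshold, numeric value synthetic
D816V	inactive	-19.8	0.5	reconstructed	FALSE	minus the WT-referenced activation baseline 19.8 +/- 0.5
D816V	active	6.5	1.3	printed	FALSE	
V620A	inactive	-13.7	0.2	printed	FALSE	
V620A	active	-12.1	0.3	printed	FALSE	
G812V	inactive	-1.6	0.5	printed	FALSE	SE reported inconsistently; see variant row
G812V	inactive	-1.6	0.4	printed	TRUE	alternate SE from discussion text
G812V	active	-12.0	0.7	printed	FALSE	
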