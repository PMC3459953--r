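family_id	individual_id	affection	cancer_type	age	is_sequenced	is_index
FAM3	FA	unknown			FALSE	FALSE
FAM3	MO	unknown			FALSE	FALSE
FAM3	S1	affected	breast	39	TRUE	TRUE
FAM3	S2	affected	breast	39	TRUE	FALSE
FAM3	S3	affected	breast	41	FALSE	FALSE
FAM3	S4	unaffected		60	FALSE	FALSE
FAM3	S5	unaffected		58	FALSE	FALSE
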