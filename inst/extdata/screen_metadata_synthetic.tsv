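screen_id	study_id	cancer_type	setting	library_scale	organism	algorithm	icb_treated
SCR01	STUDY01	skin	in_vitro	genome_scale	mouse	DrugZ	FALSE
SCR02	STUDY01	skin	in_vitro	genome_scale	mouse	DrugZ	FALSE
SCR03	STUDY02	skin	in_vitro	genome_scale	mouse	MAGeCK	FALSE
SCR04	STUDY02	skin	in_vivo	genome_scale	mouse	MAGeCK	FALSE
SCR05	STUDY03	skin	in_vitro	genome_scale	mouse	DrugZ	FALSE
SCR06	STUDY03	skin	in_vitro	genome_scale	mouse	DrugZ	FALSE
SCR07	STUDY04	skin	in_vivo	focused	mouse	BAGEL	FALSE
SCR08	STUDY05	breast	in_vitro	genome_scale	mouse	MAGeCK	FALSE
SCR09	STUDY05	breast	in_vitro	genome_scale	mouse	MAGeCK	FALSE
SCR10	STUDY06	breast	in_vitro	genome_scale	human	DrugZ	FALSE
SCR11	STUDY06	breast	in_vivo	genome_scale	mouse	DrugZ	FALSE
SCR12	STUDY07	colon	in_vitro	genome_scale	mouse	MAGeCK	FALSE
SCR13	STUDY07	colon	in_vitro	genome_scale	mouse	MAGeCK	FALSE
SCR14	STUDY08	colon	in_vitro	genome_scale	mouse	DrugZ	FALSE
SCR15	STUDY08	colon	in_vivo	focused	mouse	BAGEL	FALSE
SCR16	STUDY09	pancreas	in_vitro	genome_scale	mouse	DrugZ	FALSE
SCR17	STUDY10	lung	in_vitro	genome_scale	mouse	RIGER	FALSE
SCR18	STUDY08	colon	in_vivo	genome_scale	mouse	MAGeCK	TRUE
SCR19	STUDY11	skin	in_vivo	genome_scale	mouse	MAGeCK	TRUE
SCR20	STUDY11	skin	in_vitro	genome_scale	mouse	DrugZ	TRUE
SCR21	STUDY11	breast	in_vivo	genome_scale	mouse	DrugZ	TRUE
SCR22	STUDY10	lung	in_vivo	focused	mouse	MAGeCK	TRUE
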