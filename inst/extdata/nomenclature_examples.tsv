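id	name	is_type_strain	is_type_species	validly_published	publication_year	page_rank	is_mag
marinus_T	Methylobacter marinus	TRUE	FALSE	TRUE	1995	1	FALSE
whittenburyi_T	Methylobacter whittenburyi	TRUE	FALSE	TRUE	1995	2	FALSE
whittenburyi_2	Methylobacter whittenburyi	FALSE	FALSE	TRUE	1995	2	FALSE
methanica_T	Methylomonas methanica	TRUE	FALSE	TRUE	1970	1	FALSE
denitrificans_T	Methylomonas denitrificans	TRUE	FALSE	FALSE	2015	1	FALSE
agile_T	Methylomicrobium agile	TRUE	TRUE	TRUE	1995	1	FALSE
album_T	Methylomicrobium album	TRUE	FALSE	TRUE	1987	1	FALSE
mag_1		FALSE	FALSE	FALSE			TRUE
mag_2		FALSE	FALSE	FALSE			TRUE
noyear_a	Species alpha	FALSE	FALSE	TRUE			FALSE
noyear_b	Species beta	FALSE	FALSE	TRUE			FALSE
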