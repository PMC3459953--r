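# Mutation-screening observations: FANCC/BLM candidate-gene screen in
# BRCA1/2-negative breast cancer families vs healthy controls.
# Cohorts: full_screen_cases (all coding exons screened; n = 438 families),
# hotspot_cases (FANCC mutation-hotspot exons 2/5/7/14/15 only; n = 957
# families), controls (n = 464 healthy controls; the combined control
# denominator of 2210 for FANCC adds 654 independent-study controls and
# 1092 reference-panel genomes, all mutation-free - composition is
# metadata, not a computed quantity). External population-database
# carrier frequencies (e.g. exome-server counts 3/3510 FANCC and 4/3510
# BLM) are deliberately excluded from burden computation.
# No control rows exist because no control carried a qualifying variant.
family_or_control_id	cohort	gene	cdna_hgvs	consequence	known_pathogenic	rsid	note
FAM-FS-FANCC-1	full_screen_cases	FANCC	c.535C>T	stop_gained	FALSE		novel nonsense p.Arg179*
FAM-FS-FANCC-2	full_screen_cases	FANCC	c.553C>T	stop_gained	TRUE		known pathogenic p.Arg185*
FAM-FS-FANCC-3	full_screen_cases	FANCC	c.67delG	frameshift_coding	TRUE	rs104886459	known pathogenic p.Asp23Ilefs*23
FAM-HS-FANCC-1	hotspot_cases	FANCC	c.1661T>C	missense	TRUE	rs104886458	functionally validated pathogenic p.Leu554Pro
FAM-FS-FANCC-4	full_screen_cases	FANCC	c.554G>A	missense	FALSE		in-silico damaging p.Arg185Gln; follow-up observation, excluded from deleterious counts
FAM-FS-BLM-1	full_screen_cases	BLM	c.1993C>T	stop_gained	TRUE		reported as p.Gln645*; codon arithmetic gives 665 - transcript-numbering inconsistency, counted as truncating as published
FAM-FS-BLM-2	full_screen_cases	BLM	c.2695C>T	stop_gained	TRUE		known pathogenic p.Arg899*
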