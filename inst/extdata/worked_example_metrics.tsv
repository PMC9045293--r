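sample_id	reference_id	top_genus	top_species	group	aligned_length	query_cover	percent_identity	distance_next_species	expected_category	expected_name
iso01	Selenomonas sp.	Selenomonas	infelix		509	99	99.5	1.5	species	Selenomonas infelix
iso02	Fusobacterium necrophorum	Fusobacterium	necrophorum		454	99	98.7	2.0	genus	Fusobacterium sp.
iso03	Acinetobacter seifertii	Acinetobacter	seifertii		487	99	98.4	0.2	genus	Acinetobacter sp.
iso04	Burkholderia cenocepacia	Burkholderia	cenocepacia		487	99	98.8	0	genus	Burkholderia sp.
iso05	Butyricimonas virosa	Butyricimonas	virosa		496	100	97.8	3.0	genus	Butyricimonas sp.
iso06	Comamonas kerstersii	Comamonas	kerstersii		488	99	99.0	0.7	genus	Comamonas sp.
iso07	Clostridium perfringens	Clostridium	perfringens		479	99	98.5	5.0	genus	Clostridium sp.
iso08	Corynebacterium diphtheriae	Corynebacterium	diphtheriae		427	98	98.9	0.5	inconclusive	Inconclusive
iso09	Neisseria gonorrhoeae	Neisseria	gonorrhoeae		494	99	98.5	2.3	genus	Neisseria sp.
iso10	Pseudomonas protegens	Pseudomonas	protegens		478	100	99.4	2.0	species	Pseudomonas protegens
iso11	Streptococcus pneumoniae	Streptococcus	pneumoniae		395	100	100	0.3	inconclusive	Inconclusive
iso12	Parvimonas sp.	Parvimonas	micra		476	98	96.2	NA	inconclusive	Inconclusive
iso13	Fusobacterium sp.	Fusobacterium	nucleatum		400	100	99.5	1.5	species	Fusobacterium nucleatum
iso14	Bacteroides thetaiotaomicron	Bacteroides	thetaiotaomicron		400	100	98.9	2.9	genus	Bacteroides sp.
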