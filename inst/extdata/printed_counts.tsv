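target_id	label	numerator	denominator
t1	caudoviricetes_class_fraction	695938	741692
t2	virulent_lifestyle_fraction	410503	741692
t3	genomes_in_novel_clusters	214814	741692
t4	habitat_divergent_genus_clusters	205	327
t5	standard_code_fraction	726601	741692
t6	alt_code_fraction	15091	741692
t7	host_assigned_fraction	420907	741692
t8	generalist_fraction	262423	741692
t9	specialist_fraction	158484	741692
t10	single_directed_pair_fraction	237936	264882
t11	same_host_pair_fraction	250585	264882
t12	acquisition_incomplete_fraction	250	299
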