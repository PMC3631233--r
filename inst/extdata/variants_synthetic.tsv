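gene	chrom	position	variant_id	ref	alt	class	study_maf	ref_maf	n_affected_carriers	same_family_novel
GDF6	8	97154593	g.18328T>G	T	G	3UTR	0.005	NA	1	TRUE
GDF6	8	97154813	rs112542818	C	T	3UTR	0.026	0.003	5	FALSE
GDF6	8	97157223	rs148861809	C	G	coding-syn	0.036	0.028	7	FALSE
GDF6	8	97157413	rs121909352	G	T	missense	0.016	0.003	4	FALSE
GDF6	8	97157811	g.15169-59T>A	T	A	intronic	0.005	NA	1	TRUE
GDF6	8	97169735	g.406+2780C>T	C	T	intronic	0.01	NA	2	FALSE
GDF6	8	97170374	rs140757891	C	T	intronic	0.021	0.013	4	FALSE
GDF3	12	7842587	rs2302516	C	G	missense	0.047	0.024	7	FALSE
GDF6	8	97160001	rs_syn_common	A	G	intronic	0.12	0.1	5	FALSE
GDF6	8	97160002	g.syn_single	G	A	intronic	0.005	NA	1	FALSE
GDF6	8	97160003	rs_syn_depleted	T	C	missense	0.02	0.04	3	FALSE
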