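run_id	sample_id	pair_id	group	n_i
r1	s1	pair1	G1	4000
r2	s1	pair1	G1	5000
r3	s2	pair1	G2	5000
r4	s2	pair1	G2	6000
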