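# Operating conditions of five fed-batch BHK cultures: initial
# concentrations and feed-solution compositions, all in mM. The first feed
# started when glucose and/or glutamine fell below 0.15 mM; the second feed
# (where used) started when serine became limiting (~75 h). Flow rates were
# adjusted to keep glucose between 0.05-0.15 mM and/or glutamine between
# 0.05-0.25 mM. Fed-batch 3's second feed also carried 5x concentrated
# culture medium.
culture	item	compound	value_mM
Fed-batch 1	initial	Glc	5.5
Fed-batch 1	initial	Gln	0.2
Fed-batch 1	initial	Glu	1.6
Fed-batch 1	initial	Ser	2.3
Fed-batch 1	initial	Asp	1.4
Fed-batch 1	feed1	Glc	183.0
Fed-batch 1	feed1	Gln	15.0
Fed-batch 1	feed1	Glu	20.0
Fed-batch 2	initial	Glc	5.7
Fed-batch 2	initial	Gln	0.5
Fed-batch 2	initial	Glu	0.6
Fed-batch 2	initial	Ser	1.3
Fed-batch 2	initial	Asp	0.8
Fed-batch 2	feed1	Glc	182.0
Fed-batch 2	feed1	Gln	5.2
Fed-batch 2	feed1	Glu	31.0
Fed-batch 2	feed2	Glc	193.0
Fed-batch 2	feed2	Gln	4.5
Fed-batch 2	feed2	Glu	36.0
Fed-batch 2	feed2	Ser	33.0
Fed-batch 2	feed2	Cys	8.5
Fed-batch 3	initial	Glc	0.18
Fed-batch 3	initial	Gln	0.42
Fed-batch 3	initial	Glu	0.82
Fed-batch 3	initial	Ser	1.30
Fed-batch 3	initial	Asp	0.65
Fed-batch 3	feed1	Glc	150.0
Fed-batch 3	feed1	Gln	4.2
Fed-batch 3	feed1	Glu	29.2
Fed-batch 3	feed2	Glc	160.0
Fed-batch 3	feed2	Gln	5.4
Fed-batch 3	feed2	Glu	25.6
Fed-batch 4	initial	Glc	6.2
Fed-batch 4	initial	Gln	3.9
Fed-batch 4	initial	Glu	0.6
Fed-batch 4	initial	Ser	1.4
Fed-batch 4	initial	Asp	0.8
Fed-batch 4	feed1	Glc	198.0
Fed-batch 4	feed2	Glc	156.0
Fed-batch 4	feed2	Gln	42.8
Fed-batch 5	initial	Glc	4.8
Fed-batch 5	initial	Gln	0.1
Fed-batch 5	initial	Glu	4.0
Fed-batch 5	initial	Ser	1.4
Fed-batch 5	initial	Asp	0.8
Fed-batch 5	feed1	Glc	183.0
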