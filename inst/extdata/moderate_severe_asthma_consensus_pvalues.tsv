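gene_id	sherlock_discovery_p	sherlock_rep1_p	sherlock_rep2_p	gene_based_p	null_control_p	documented
HLA-DRB5	7.93e-7	1.60e-3	4.09e-6	7.57e-10	0.11	yes
HLA-DRB1	7.93e-7	4.64e-6	4.09e-6	1.41e-11	0.59	yes
GNGT2	1.11e-5	2.30e-4	1.83e-2	1.42e-2	0.48	yes
HLA-DQA1	2.85e-5	7.73e-7	1.49e-3	2.90e-23	0.58	yes
SLC22A5	1.85e-4	3.87e-5	2.66e-5	1.23e-6	0.46	yes
STAT6	2.19e-4	2.75e-2	3.31e-2	1.94e-11	0.97	yes
MPI	1.90e-3	2.02e-2	2.39e-2	1.12e-5	0.84	no
TLR6	3.63e-3	3.54e-3	6.69e-3	4.10e-2	0.93	yes
DECR2	1.62e-2	4.32e-2	1.58e-4	2.22e-2	0.78	no
LNPEP	2.28e-2	5.55e-4	4.33e-2	3.98e-2	0.46	no
TTC19	2.52e-2	1.81e-2	2.20e-2	3.23e-2	0.30	no
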