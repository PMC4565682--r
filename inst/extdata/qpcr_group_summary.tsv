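# RT-qPCR absolute copy-number group summaries (healthy controls vs breast
# cancer cases) for four circulating miRNA assays, measured in total RNA
# and in the enriched small-RNA fraction, for an initial validation sample
# set and the expanded full set.
assay_id	fraction	sample_set	mean_control	sd_control	mean_case	sd_case
miR-195	total	initial	6.86e7	8.53e7	9.48e7	8.36e7
miR-16	total	initial	2.51e8	2.70e8	2.56e8	2.12e8
miR-320a	total	initial	1.53e8	1.83e8	6.63e7	5.49e7
let-7b	total	initial	2.22e7	2.93e7	1.11e7	8.21e6
miR-195	enriched	initial	4.92e6	5.36e6	8.13e6	7.36e6
miR-16	enriched	initial	4.76e7	5.36e7	5.18e7	3.46e7
miR-320a	enriched	initial	4.24e7	3.84e7	7.78e6	1.24e7
let-7b	enriched	initial	9.15e6	1.61e7	1.08e6	7.61e5
miR-320a	total	full	1.58e8	1.83e8	6.63e7	5.84e7
miR-320a	enriched	full	4.20e7	4.03e7	4.72e6	2.20e6
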