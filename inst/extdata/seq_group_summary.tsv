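# Whole-blood small-RNA sequencing group summaries for eight circulating
# miRNAs from a two-cohort study (healthy controls vs breast cancer cases):
# per-group mean and SD of expression counts with the group sizes used for
# differential-expression testing.
mirna	mean_control	sd_control	mean_case	sd_case	n_control	n_case
miR-320a	845	528	368	379	26	15
miR-140	3687	1407	2141	1190	26	15
let-7b	606	441	424	401	26	15
miR-30d	4137	1532	2255	896	26	15
miR-150	2176	1092	1388	617	26	15
miR-22	3070	1301	1904	647	26	15
miR-425	2485	892	2087	807	26	15
miR-191	30283	13812	16598	10679	26	15
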