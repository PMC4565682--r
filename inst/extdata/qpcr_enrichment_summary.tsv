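# Impact of small-RNA size-selection enrichment on measured absolute copy
# numbers: per-assay mean and SD of copies in total RNA and after
# enrichment, across the same clinical samples.
assay_id	mean_total	sd_total	mean_enriched	sd_enriched
miR-195	6.88e7	8.34e7	5.87e6	6.00e6
miR-16	2.52e8	2.56e8	4.88e7	4.96e7
miR-320a	1.30e8	1.60e8	3.16e7	3.80e7
let-7b	1.99e7	2.66e7	3.64e6	4.83e6
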