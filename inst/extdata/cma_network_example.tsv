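# Illustrative (synthetic) CMA network fixture — NOT a curated/published gene list.
# LAMP2A, the rate-limiting CMA receptor, carries weight 2; all other
# components weight 1.  direction +1 = promotes CMA activity, -1 = represses.
gene	weight	direction
LAMP2A	2	1
HSPA8	1	1
DNAJB1	1	1
BAG1	1	1
CTSA	1	1
RARA	1	-1
AKT1	1	-1
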