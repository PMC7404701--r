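source	activity_code	A	printed_bin
cow	ah	0.834	major
cow	dpp	0.854	major
cow	am	0.214	moderate
cow	re	0.214	moderate
cow	at	0.238	moderate
cow	apr	0.002	minor
cow	35pd	0.002	minor
cow	im	0.003	minor
cow	ren	0.006	minor
cow	ne	0.009	minor
cow	emb	0.014	minor
cow	che	0.037	minor
cow	glui	0.041	minor
cow	inh	0.057	minor
cow	ao	0.059	minor
cow	st	0.069	minor
cow	dpp3	0.073	minor
pig	dpp	0.846	major
pig	ah	0.847	major
pig	am	0.216	moderate
pig	re	0.216	moderate
pig	at	0.238	moderate
pig	emb	0.001	minor
pig	apr	0.002	minor
pig	35pd	0.002	minor
pig	im	0.003	minor
pig	ren	0.006	minor
pig	st	0.007	minor
pig	ne	0.008	minor
pig	che	0.038	minor
pig	glui	0.042	minor
pig	inh	0.058	minor
pig	ao	0.060	minor
pig	dpp3	0.076	minor
sheep	ah	0.833	major
sheep	dpp	0.845	major
sheep	am	0.198	moderate
sheep	re	0.198	moderate
sheep	at	0.215	moderate
sheep	emb	0.001	minor
sheep	im	0.001	minor
sheep	35pd	0.002	minor
sheep	apr	0.003	minor
sheep	ren	0.006	minor
sheep	st	0.007	minor
sheep	ne	0.008	minor
sheep	che	0.033	minor
sheep	glui	0.045	minor
sheep	inh	0.052	minor
sheep	ao	0.059	minor
sheep	dpp3	0.073	minor
chicken	ah	0.843	major
chicken	dpp	0.852	major
chicken	am	0.210	moderate
chicken	re	0.210	moderate
chicken	at	0.223	moderate
chicken	lig	0.001	minor
chicken	apr	0.002	minor
chicken	35pd	0.002	minor
chicken	emb	0.002	minor
chicken	im	0.003	minor
chicken	ren	0.006	minor
chicken	is	0.006	minor
chicken	st	0.006	minor
chicken	ne	0.008	minor
chicken	glui	0.040	minor
chicken	che	0.040	minor
chicken	inh	0.057	minor
chicken	ao	0.061	minor
chicken	dpp3	0.075	minor
duck	ah	0.847	major
duck	dpp	0.870	major
duck	at	0.240	moderate
duck	am	0.210	moderate
duck	re	0.210	moderate
duck	hypl	0.002	minor
duck	35pd	0.002	minor
duck	lig	0.003	minor
duck	emb	0.004	minor
duck	apr	0.007	minor
duck	ren	0.011	minor
duck	glui	0.033	minor
duck	che	0.033	minor
duck	inh	0.046	minor
duck	ao	0.057	minor
duck	dpp3	0.083	minor
horse	ah	0.843	major
horse	dpp	0.843	major
horse	am	0.215	moderate
horse	re	0.215	moderate
horse	at	0.238	moderate
horse	emb	0.001	minor
horse	35pd	0.002	minor
horse	apr	0.003	minor
horse	im	0.003	minor
horse	ren	0.006	minor
horse	st	0.007	minor
horse	ne	0.009	minor
horse	che	0.037	minor
horse	glui	0.041	minor
horse	inh	0.058	minor
horse	ao	0.058	minor
horse	dpp3	0.073	minor
salmon	dpp	0.798	major
salmon	ah	0.799	major
salmon	at	0.170	moderate
salmon	am	0.170	moderate
salmon	re	0.170	moderate
salmon	emb	0.002	minor
salmon	is	0.002	minor
salmon	35pd	0.003	minor
salmon	lig	0.003	minor
salmon	apr	0.003	minor
salmon	st	0.005	minor
salmon	ne	0.008	minor
salmon	ren	0.008	minor
salmon	che	0.023	minor
salmon	glui	0.029	minor
salmon	ao	0.053	minor
salmon	dpp3	0.074	minor
rainbow_trout	dpp	0.810	major
rainbow_trout	ah	0.846	major
rainbow_trout	am	0.161	moderate
rainbow_trout	re	0.162	moderate
rainbow_trout	at	0.181	moderate
rainbow_trout	hypl	0.001	minor
rainbow_trout	lig	0.002	minor
rainbow_trout	emb	0.003	minor
rainbow_trout	35pd	0.003	minor
rainbow_trout	apr	0.006	minor
rainbow_trout	st	0.008	minor
rainbow_trout	ne	0.009	minor
rainbow_trout	ren	0.013	minor
rainbow_trout	glui	0.015	minor
rainbow_trout	che	0.018	minor
rainbow_trout	inh	0.020	minor
rainbow_trout	ao	0.034	minor
rainbow_trout	dpp3	0.071	minor
goat	ah	0.842	major
goat	dpp	0.849	major
goat	am	0.213	moderate
goat	re	0.213	moderate
goat	at	0.273	moderate
goat	emb	0.001	minor
goat	apr	0.002	minor
goat	35pd	0.002	minor
goat	im	0.003	minor
goat	ren	0.006	minor
goat	st	0.007	minor
goat	ne	0.009	minor
goat	che	0.037	minor
goat	glui	0.041	minor
goat	inh	0.057	minor
goat	ao	0.058	minor
goat	dpp3	0.074	minor
rabbit	ah	0.834	major
rabbit	dpp	0.849	major
rabbit	am	0.199	moderate
rabbit	re	0.199	moderate
rabbit	at	0.215	moderate
rabbit	emb	0.001	minor
rabbit	im	0.001	minor
rabbit	35pd	0.002	minor
rabbit	apr	0.003	minor
rabbit	ren	0.006	minor
rabbit	st	0.007	minor
rabbit	ne	0.008	minor
rabbit	che	0.034	minor
rabbit	glui	0.045	minor
rabbit	inh	0.052	minor
rabbit	ao	0.059	minor
rabbit	dpp3	0.073	minor
turkey	dpp	0.822	major
turkey	ah	0.841	major
turkey	am	0.192	moderate
turkey	re	0.192	moderate
turkey	at	0.220	moderate
turkey	hypl	0.002	minor
turkey	lig	0.003	minor
turkey	35pd	0.003	minor
turkey	emb	0.004	minor
turkey	apr	0.007	minor
turkey	ne	0.009	minor
turkey	st	0.012	minor
turkey	ren	0.014	minor
turkey	che	0.027	minor
turkey	glui	0.030	minor
turkey	inh	0.041	minor
turkey	ao	0.059	minor
turkey	dpp3	0.082	minor
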