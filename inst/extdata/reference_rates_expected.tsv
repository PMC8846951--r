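# Expected fitted family and parameters per enzyme for the 19-reference
# worked example, plus the published query EZS values of the two Gulf of
# Mexico samples (documentation only: the query count tables are not part
# of the fixture, so those EZS values cannot be recomputed from it).
ec	family	p1	p2	ezs_d18_max	ezs_a04_aaiw
1.1.1.35	normal	2291.17784	176.84802	-0.220768	3.27996
1.14.13.7	lognormal	3.295168	0.4076202	1.5988	2.18523
1.3.1.32	gamma	2.683552	0.08778131	1.14147	3.7638
2.8.3.8	weibull	2.555658	86.05314	0.838235	2.8628
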