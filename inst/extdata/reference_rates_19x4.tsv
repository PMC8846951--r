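# Per-million annotation rates of four enzymes across the 19 reference
# ocean-water metagenomes (M1-M19) used by the worked example.
metagenome	1.1.1.35	1.14.13.7	1.3.1.32	2.8.3.8
M1	2104.258	21.69339	21.693386	65.08016
M2	2111.734	34.36254	28.114808	93.71603
M3	2213.504	28.22319	32.255073	76.6058
M4	2089.64	22.5907	22.590702	71.53722
M5	2594.575	33.75057	29.531753	42.18822
M6	2365.485	15.87574	12.70059	41.27692
M7	1939.527	38.25496	49.73145	38.25496
M8	2174.35	20.60995	41.219903	103.04976
M9	2206.178	15.68373	47.051197	151.60941
M10	2656.021	16.39519	2.732532	19.12772
M11	2541.855	52.83302	23.481344	70.44403
M12	2363.248	55.19262	85.297689	120.42027
M13	2349.213	25.28301	18.962259	63.20753
M14	2267.837	20.76774	33.228387	87.22452
M15	2315.387	64.46553	53.721273	118.1868
M16	2339.845	21.02557	15.018262	45.05479
M17	2412.827	20.0512	20.051197	66.83732
M18	2169.387	25.7647	15.458818	77.29409
M19	2317.505	28.00611	28.006105	98.02137
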