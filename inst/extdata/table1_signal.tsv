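category	trait	K	P	lambda	best_model	alternatives
composition	tges	0.426	0.001	0.874	lambda	
composition	tmax	0.988	0.001	1.000	EB	BM
composition	tmin	0.932	0.001	0.998	BM	lambda,EB
composition	zel	0.553	0.001	0.862	OU	lambda
composition	zeltges	0.533	0.001	0.808	OU	lambda
composition	zeltype	0.276	0.058	0.627	lambda	
frequency	fmax	0.428	0.001	0.800	lambda	
frequency	fmin	0.299	0.020	0.877	lambda	
frequency	fmean	0.371	0.001	0.966	lambda	
frequency	df	0.142	0.356	0.743	lambda	
frequency	dfmax	0.407	0.001	0.850	lambda	
frequency	dfmin	0.374	0.001	0.923	lambda	
frequency	fmodend	0.128	0.511	0.355	lambda	white
derived	complexity1	0.177	0.212	1.000	lambda	
derived	complexity2	0.646	0.001	0.977	lambda	
derived	complexity3	0.364	0.001	0.755	lambda	
pc	PCall1	0.569	0.001	0.986	lambda	
pc	PCall2	0.287	0.013	0.804	lambda	
pc	PCcomp1	0.719	0.001	0.994	lambda	
pc	PCcomp2	0.469	0.001	0.865	lambda	
pc	PCfreq1	0.410	0.001	0.979	lambda	
pc	PCfreq2	0.199	0.126	0.850	lambda	
explanatory	length	0.948	0.001	1.000	BM	
explanatory	mass	1.055	0.001	1.000	BM	EB
explanatory	migration	0.386	0.002	0.511	OU	
explanatory	region	0.659	0.001	0.993	lambda	
explanatory	lat_max	0.318	0.001	0.588	lambda	
explanatory	lat_min	0.119	0.552	0.990	lambda	
explanatory	lat_mean	0.229	0.087	1.000	lambda	
explanatory	lat_equator	0.183	0.181	1.000	lambda	
explanatory	long_max	0.320	0.002	0.469	lambda	OU
explanatory	long_min	0.459	0.001	0.700	lambda	
explanatory	long_mean	0.396	0.001	0.642	lambda	
explanatory	ele_max	0.385	0.001	0.663	OU	
explanatory	ele_min	0.380	0.002	0.636	OU	
explanatory	ele_mean	0.432	0.001	0.783	OU	
explanatory	habitat	0.782	0.001	1.000	BM	OU
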