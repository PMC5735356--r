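library	category	count	percent
TW	high_quality_reads	11861547	100
TW	three_prime_adapter_null	27731	0.23
TW	insert_null	8951	0.08
TW	five_prime_contaminant	205353	1.73
TW	shorter_than_18	595179	5.02
TW	polyA	907	0.01
TW	clean	11023426	92.93
12h	high_quality_reads	11872699	100
12h	three_prime_adapter_null	45757	0.39
12h	insert_null	4048	0.03
12h	five_prime_contaminant	61614	0.52
12h	shorter_than_18	105692	0.89
12h	polyA	142	0
12h	clean	11655446	98.17
18h	high_quality_reads	11944980	100
18h	three_prime_adapter_null	3422	0.03
18h	insert_null	6282	0.05
18h	five_prime_contaminant	49186	0.41
18h	shorter_than_18	65511	0.55
18h	polyA	130	0
18h	clean	11820449	98.96
24h	high_quality_reads	11956814	100
24h	three_prime_adapter_null	2394	0.02
24h	insert_null	4351	0.04
24h	five_prime_contaminant	25940	0.22
24h	shorter_than_18	131053	1.1
24h	polyA	134	0
24h	clean	11792942	98.63
36h	high_quality_reads	11866077	100
36h	three_prime_adapter_null	29205	0.25
36h	insert_null	10499	0.09
36h	five_prime_contaminant	75571	0.64
36h	shorter_than_18	522744	4.41
36h	polyA	275	0
36h	clean	11227783	94.62
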