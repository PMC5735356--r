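mirna_id	treatment	control_tpm	treatment_tpm	log2fc	pvalue	fdr
pxy-mir-7b-5p	12h	17.64	3.92	-2.169925	3.29e-20	2.44e-19
pxy-mir-2768-3p	12h	14.23	4.35	-1.709848	1.94e-12	9.50e-12
pxy-mir-79-3p	12h	26.74	8.92	-1.583884	5.50e-20	3.82e-19
pxy-mir-8507-3p	12h	124.38	43.84	-1.504435	8.98e-81	1.61e-79
pxy-mir-2a-3p	12h	11.49	5.11	-1.168984	2.08e-06	6.78e-06
pxy-mir-7b-5p	18h	17.64	2.6	-2.762267033	5.81e-27	5.52e-26
pxy-mir-2768-3p	18h	14.23	5.1	-1.48036651	1.35e-10	6.30e-10
pxy-mir-79-3p	18h	26.74	9.06	-1.56141651	4.42e-20	3.36e-19
pxy-mir-8507-3p	18h	124.38	57.56	-1.111616025	2.44e-52	3.97e-51
pxy-mir-2a-3p	18h	11.49	2.39	-2.265296275	1.16e-14	6.63e-14
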