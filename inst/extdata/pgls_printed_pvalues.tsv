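domain	temp	gc_index	slope	p	p_bh
bacteria	Tmax	GC_w	7.1e-4	7.1e-4	9.4e-4
bacteria	Topt	GC_w	5.7e-4	0.009	0.011
bacteria	Tmin	GC_w	2.8e-4	0.156	0.226
bacteria	Tmax	GC_p	6.6e-4	0.002	0.002
bacteria	Topt	GC_p	5.3e-4	0.015	0.016
bacteria	Tmin	GC_p	2.5e-4	0.202	0.231
bacteria	Tmax	GC_4	0.001	0.003	0.003
bacteria	Topt	GC_4	0.001	0.016	0.016
bacteria	Tmin	GC_4	5.5e-4	0.239	0.239
bacteria	Tmax	GC_non	8.0e-4	1.7e-4	2.8e-4
bacteria	Topt	GC_non	6.4e-4	0.004	0.006
bacteria	Tmin	GC_non	2.7e-4	0.170	0.226
bacteria	Tmax	GC_tRNA	4.1e-4	2.2e-16	5.9e-16
bacteria	Topt	GC_tRNA	3.9e-4	2.6e-14	6.9e-14
bacteria	Tmin	GC_tRNA	1.5e-4	9.1e-4	0.002
bacteria	Tmax	GC_5S	5.5e-4	1.2e-6	2.4e-6
bacteria	Topt	GC_5S	4.4e-4	1.4e-4	2.9e-4
bacteria	Tmin	GC_5S	3.5e-4	0.001	0.002
bacteria	Tmax	GC_16S	5.4e-4	2.2e-16	5.9e-16
bacteria	Topt	GC_16S	5.2e-4	2.2e-16	8.8e-16
bacteria	Tmin	GC_16S	4.6e-4	2.2e-16	8.8e-16
bacteria	Tmax	GC_23S	6.6e-4	2.2e-16	5.9e-16
bacteria	Topt	GC_23S	6.5e-4	2.2e-16	8.8e-16
bacteria	Tmin	GC_23S	4.9e-4	2.2e-16	8.8e-16
archaea	Tmax	GC_w	6.6e-4	0.115	0.153
archaea	Topt	GC_w	3.3e-4	0.377	0.503
archaea	Tmin	GC_w	5.2e-4	0.126	0.168
archaea	Tmax	GC_p	5.6e-4	0.183	0.209
archaea	Topt	GC_p	2.4e-4	0.522	0.597
archaea	Tmin	GC_p	4.6e-4	0.180	0.205
archaea	Tmax	GC_4	9.9e-4	0.321	0.321
archaea	Topt	GC_4	2.2e-4	0.806	0.806
archaea	Tmin	GC_4	6.9e-4	0.393	0.393
archaea	Tmax	GC_non	9.1e-4	0.025	0.041
archaea	Topt	GC_non	6.4e-4	0.080	0.129
archaea	Tmin	GC_non	6.5e-4	0.048	0.077
archaea	Tmax	GC_tRNA	7.1e-4	1.8e-11	7.2e-11
archaea	Topt	GC_tRNA	5.0e-4	2.5e-7	6.7e-7
archaea	Tmin	GC_tRNA	4.2e-4	1.8e-6	4.7e-6
archaea	Tmax	GC_5S	0.001	1.9e-5	3.9e-5
archaea	Topt	GC_5S	8.9e-4	1.6e-4	3.2e-4
archaea	Tmin	GC_5S	6.1e-4	0.005	0.010
archaea	Tmax	GC_16S	8.2e-4	3.9e-11	1.0e-10
archaea	Topt	GC_16S	7.2e-4	1.1e-10	4.5e-10
archaea	Tmin	GC_16S	5.5e-4	8.5e-8	3.4e-7
archaea	Tmax	GC_23S	0.001	2.2e-16	1.8e-15
archaea	Topt	GC_23S	0.001	1.2e-14	9.5e-14
archaea	Tmin	GC_23S	8.3e-4	8.0e-11	6.4e-10
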