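accession	origin	r_volume	gradient_amp
ALB_SYN	plasma_liver	177	1.6
SYN_CNS_001	cns	4.214868860128044	1
SYN_CNS_002	cns	4.567506502534332	1
SYN_CNS_003	cns	0.07614391120884136	1
SYN_CNS_004	cns	0.0692578429394269	1
SYN_PLAS_001	plasma_liver	50.55286131448105	1.6
SYN_PLAS_002	plasma_liver	3459.2412424093686	1.6
SYN_PLAS_003	plasma_liver	149.83527793423647	1.6
SYN_PLAS_004	plasma_liver	658.9851082183662	1.6
SYN_BLOO_001	blood_cellular	0.11893481837186198	1
SYN_BLOO_002	blood_cellular	0.5822472851178994	1
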