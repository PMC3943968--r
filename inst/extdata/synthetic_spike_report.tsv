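accession	reference	spike_0.5	spike_2
ALB_SYN	215.38913699147142	403.4961177513341	811.5146676115969
SYN_CNS_001	449.8090259150415	410.7440076838722	400.56299632572245
SYN_CNS_002	239.37998411059738	208.25358936759096	210.63857034926397
SYN_CNS_003	6.020777704541936	7.196172550516149	7.226519375746253
SYN_CNS_004	47.92084979579518	44.54497832922257	39.0470374044404
SYN_PLAS_001	9.985849738673046	12.743938278679739	17.021970750250418
SYN_PLAS_002	10.96578183485947	262.3693979354629	838.6712774584338
SYN_PLAS_003	127.03415634976089	224.916118272234	515.7356583030918
SYN_PLAS_004	187.92259452169822	767.7795119909407	2202.0000221312175
SYN_BLOO_001	9.208257799234248	354.7508956006933	1283.5461952065593
SYN_BLOO_002	1.684302335806737	15.785210264255603	56.72028087440782
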