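# label: G3G3G3G3G
# seed: 22
# convention: monoisotopic
# precursor_mz: 1089.5305
mz	intensity
211.0947	0.0486
227.0896	1.0000
241.1052	0.7628
259.1158	0.8102
315.1420	0.0646
401.1788	0.0452
415.1944	0.0784
445.2050	0.8063
463.2156	0.7200
519.2418	0.0250
605.2786	0.0454
619.2942	0.0573
649.3048	0.6880
667.3153	0.7688
723.3415	0.0680
823.3940	0.0756
853.4045	0.7356
871.4151	0.6094
927.4413	0.0308
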