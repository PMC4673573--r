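# label: G4G4G4G4G
# seed: 21
# convention: monoisotopic
# precursor_mz: 1089.5305
mz	intensity
211.0947	0.8994
227.0896	0.0624
241.1052	0.5964
259.1158	0.5548
315.1420	0.0305
329.1577	1.0000
401.1788	0.9312
415.1944	0.0766
431.1893	0.5328
445.2050	0.8150
463.2156	0.7680
519.2418	0.0372
533.2574	0.7548
605.2786	0.8227
619.2942	0.0569
635.2891	0.8941
649.3048	0.9688
667.3153	0.7898
723.3415	0.0672
737.3572	0.8627
809.3783	0.8404
823.3940	0.0766
839.3889	0.8787
853.4045	0.9257
871.4151	0.6125
927.4413	0.0594
941.4570	0.6723
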