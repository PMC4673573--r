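fraction	t_glc	glc3	glc4	glcol3	glcol4
C3	1	0.96	-	-	1.46
C4	1	0.93	0.90	-	1.19
C5-b	1	1.72	1.14	-	0.53
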