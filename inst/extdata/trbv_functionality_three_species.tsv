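gene	subgroup	dromedarius	ferus	bactrianus
TRBV1	TRBV1	F	P	F
TRBV2	TRBV2	F	F	F
TRBV3	TRBV3	P	P	P
TRBV5S1	TRBV5	F	F	F
TRBV5S2	TRBV5	F	F	F
TRBV5S3	TRBV5	F	F	F
TRBV6	TRBV6	F	F	F
TRBV7S1	TRBV7	F	P	P
TRBV7S2	TRBV7	F	F	F
TRBV8	TRBV8	F	F	F
TRBV9	TRBV13	P	P	P
TRBV10	TRBV10	F	F	F
TRBV11	TRBV11	F	F	F
TRBV12S1	TRBV12	P	F	P
TRBV12S2	TRBV12	P	P	P
TRBV14	TRBV14	P	F	F
TRBV15S1	TRBV15	F	F	F
TRBV15S2	TRBV15	F	-	nd
TRBV16	TRBV16	F	P	F
TRBV19	TRBV19	F	F	F
TRBV20	TRBV20	F	ORF	nd
TRBV21S1	TRBV21	F	F	F
TRBV21S2	TRBV21	F	-	F
TRBV21S3	TRBV21	P	-	P
TRBV22	TRBV22	F	F	F
TRBV23	TRBV23	P	P	P
TRBV24	TRBV24	P	F	F
TRBV25	TRBV25	F	F	F
TRBV26	TRBV26	F	P	F
TRBV27	TRBV27	F	F	F
TRBV28	TRBV28	F	P	F
TRBV29	TRBV29	F	F	F
TRBV30	TRBV30	F	F	F
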