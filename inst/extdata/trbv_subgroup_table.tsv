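subgroup	human	dromedarius	ferus	bactrianus
TRBV1	1 (P)	1	1 (P)	1
TRBV2	1	1	1	1
TRBV3	2	1 (P)	1 (P)	1 (P)
TRBV4	3	-	-	-
TRBV5	8	3	3	3
TRBV6	9	1	1	1
TRBV7	9	2	1 (P) + 1	1 (P) + 1
TRBV8	2	1	1	1
TRBV9	1	(TRBV5S2)	(TRBV5S2)	(TRBV5S2)
TRBV10	3	1	1	1
TRBV11	3	1	1	1
TRBV12	5	2 (P)	1 (P) + 1	2 (P)
TRBV13	1	1 (TRBV9 P)	1 (TRBV9 P)	1 (TRBV9 P)
TRBV14	1	1 (P)	1	1
TRBV15	1	2	1	1 + 1 (nd)
TRBV16	1	1	1 (P)	1
TRBV17	1 (ORF)	-	-	-
TRBV18	1	-	-	-
TRBV19	1	1	1	1
TRBV20	1	1	1 (ORF)	1 (nd)
TRBV21	1	2 + 1 (P)	1	2 + 1 (P)
TRBV22	1	1	1	1
TRBV23	1	1 (P)	1 (P)	1 (P)
TRBV24	1	1 (P)	1	1
TRBV25	1	1	1	1
TRBV26	1	1	1 (P)	1
TRBV27	1	1	1	1
TRBV28	1	1	1 (P)	1
TRBV29	1	1	1	1
TRBV30	1	1	1	1
TOTAL	66	33	30	33
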