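isolate	gene	length_bp	ct_mean	is_reference
KY7-11	12S	165	11.50	FALSE
KY7-11	COX1-ex3	121	11.74	FALSE
KY7-11	COX1-alpha	227	15.80	FALSE
KY7-11	COX1-beta	234	25.98	FALSE
KY7-11	TUB	140	16.55	TRUE
GB192	12S	165	12.61	FALSE
GB192	COX1-ex3	121	13.15	FALSE
GB192	COX1-alpha	227	17.43	FALSE
GB192	COX1-beta	234	24.21	FALSE
GB192	TUB	140	17.98	TRUE
XY18-9	12S	165	12.82	FALSE
XY18-9	COX1-ex3	121	12.87	FALSE
XY18-9	COX1-alpha	227	22.54	FALSE
XY18-9	COX1-beta	234	30.69	FALSE
XY18-9	TUB	140	18.11	TRUE
KY7-21	12S	165	10.90	FALSE
KY7-21	COX1-ex3	121	10.94	FALSE
KY7-21	COX1-alpha	227	28.13	FALSE
KY7-21	COX1-beta	234	13.28	FALSE
KY7-21	TUB	140	16.16	TRUE
JN1-13	12S	165	12.55	FALSE
JN1-13	COX1-ex3	121	12.60	FALSE
JN1-13	COX1-alpha	227	31.73	FALSE
JN1-13	COX1-beta	234	16.46	FALSE
JN1-13	TUB	140	18.16	TRUE
SL3-13	12S	165	11.33	FALSE
SL3-13	COX1-ex3	121	11.65	FALSE
SL3-13	COX1-alpha	227	32.55	FALSE
SL3-13	COX1-beta	234	14.25	FALSE
SL3-13	TUB	140	17.80	TRUE
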