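sample_id	histology	TP53	NF1	BRCA1	RB1	BRCA2
SC-1	SC	LOH	LOH	LOH	LOH	LOH
SC-2	SC	LOH	LOH	LOH	LOH	LOH
SC-3	SC	LOH	LOH	LOH	LOH	LOH
SC-4	SC	LOH	LOH	LOH	LOH	LOH
SC-5	SC	LOH	LOH	LOH	LOH	LOH
SC-6	SC	LOH	LOH	LOH	LOH	LOH
SC-7	SC	CNN LOH	LOH	LOH	LOH	LOH
SC-8	SC	CNN LOH	CNN LOH	CNN LOH	LOH	LOH
SC-9	SC	LOH	LOH	LOH	nl	nl
SC-10	SC	LOH	CNN LOH	LOH	nl	nl
SC-11	SC	CNN LOH	LOH	LOH	nl	nl
SC-12	SC	CNN LOH	nl	nl	nl	nl
SC-13	SC	nl	nl	nl	nl	nl
CCC-1	CCC	LOH	nl	nl	LOH	LOH
CCC-2	CCC	LOH	nl	nl	LOH	LOH
CCC-3	CCC	LOH	nl	nl	LOH	nl
CCC-4	CCC	LOH	nl	nl	nl	nl
CCC-5	CCC	LOH	nl	nl	nl	nl
CCC-6	CCC	LOH	nl	nl	nl	nl
CCC-7	CCC	nl	nl	nl	LOH	LOH
CCC-8	CCC	nl	nl	nl	CNN LOH	CNN LOH
CCC-9	CCC	nl	nl	nl	nl	nl
CCC-10	CCC	nl	nl	nl	nl	nl
CCC-11	CCC	nl	nl	nl	nl	nl
CCC-12	CCC	nl	nl	nl	nl	nl
CCC-13	CCC	nl	nl	nl	nl	nl
CCC-14	CCC	nl	nl	nl	nl	nl
CCC-15	CCC	nl	nl	nl	nl	nl
CCC-16	CCC	nl	nl	nl	nl	nl
CCC-17	CCC	nl	nl	nl	nl	nl
CCC-18	CCC	nl	nl	nl	nl	nl
CCC-19	CCC	nl	nl	nl	nl	nl
CCC-20	CCC	nl	nl	nl	nl	nl
CCC-21	CCC	nl	nl	nl	nl	nl
CCC-22	CCC	nl	nl	nl	nl	nl
CCC-23	CCC	nl	nl	nl	nl	nl
CCC-24	CCC	nl	nl	nl	nl	nl
CCC-25	CCC	nl	nl	nl	nl	nl
CCC-26	CCC	nl	nl	nl	nl	nl
CCC-27	CCC	nl	nl	nl	nl	nl
CCC-28	CCC	nl	nl	nl	nl	nl
CCC-29	CCC	nl	nl	nl	nl	nl
CCC-30	CCC	nl	nl	nl	nl	nl
CCC-31	CCC	nl	nl	nl	nl	nl
EC-1	EC	LOH	LOH	LOH	CNN LOH	LOH
EC-2	EC	LOH	nl	nl	nl	nl
EC-3	EC	LOH	nl	LOH	nl	nl
EC-4	EC	CNN LOH	LOH	CNN LOH	LOH	nl
EC-5	EC	CNN LOH	LOH	LOH	nl	nl
EC-6	EC	nl	nl	nl	nl	nl
EC-7	EC	nl	nl	nl	nl	nl
EC-8	EC	nl	nl	nl	nl	nl
EC-9	EC	nl	nl	nl	nl	nl
EC-10	EC	nl	nl	nl	nl	nl
EC-11	EC	nl	nl	nl	nl	nl
EC-12	EC	nl	nl	nl	nl	nl
EC-13	EC	nl	nl	nl	nl	nl
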