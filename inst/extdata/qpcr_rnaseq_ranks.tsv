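biofluid	circrna	mean_ct	qpcr_rank	mean_jrpm	rnaseq_rank
plasma	circUXS1	27.4	1	51.21	15
plasma	circNRIP1	27.96	2	89.8	10
plasma	circARHGEF12	28.04	3	110.13	5
plasma	circMCU	28.53	4	415.78	1
plasma	circPCMTD1	28.8	5	60.09	13
plasma	circFIP1L1-1	28.99	6	250.67	2
plasma	circRHBDD1	29.75	7	217.81	4
plasma	circETFA	30.05	8	66.35	11
plasma	circPRKCB	30.16	9	65.81	12
plasma	circSMARCA5	30.64	10	99.59	9
plasma	circSIAE	31.41	11	234.59	3
plasma	circYPEL2	31.88	12	51.44	14
plasma	circCDK17	32.12	13	102.04	7
plasma	circFIP1L1-2	32.36	14	100.46	8
plasma	circPOMT1	32.6	15	106.79	6
urine	circARHGEF12	31.27	1	5.27	15
urine	circRBM23	31.46	2	8.21	5
urine	circUBAP2	31.68	3	6.49	10
urine	circCDYL2	31.93	4	6.72	8
urine	circPAPOLA	32.64	5	6.61	9
urine	circSMARCA5	32.72	6	7.85	6
urine	circRHBDD1	33.22	7	10.72	3
urine	circYPEL2	33.25	8	9.3	4
urine	circDMXL1	33.63	9	6.29	11
urine	circPOMT1	33.67	10	28.46	2
urine	circFARSA	33.75	11	7.5	7
urine	circFIP1L1-2	33.81	12	5.61	14
urine	circSTK39	34.45	13	6.24	12
urine	circMYO5B	NA	14	5.7	13
urine	circPHC3	NA	15	81.19	1
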