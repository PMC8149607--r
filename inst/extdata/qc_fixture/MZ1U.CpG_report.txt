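chrS	1000	+	8	2	CpG	CGA
chrS	1001	-	7	3	CpG	CGT
chrS	1100	+	8	2	CpG	CGA
chrS	1101	-	7	3	CpG	CGT
chrS	1200	+	8	2	CpG	CGA
chrS	1250	+	3	4	CHH	CAT
chrS	1201	-	7	3	CpG	CGT
chrS	1300	+	8	2	CpG	CGA
chrS	1301	-	7	3	CpG	CGT
chrS	1400	+	8	2	CpG	CGA
chrS	1401	-	7	3	CpG	CGT
chrS	1500	+	8	2	CpG	CGA
chrS	1501	-	7	3	CpG	CGT
chrS	1600	+	8	2	CpG	CGA
chrS	1601	-	7	3	CpG	CGT
chrS	1700	+	8	2	CpG	CGA
chrS	1701	-	7	3	CpG	CGT
chrS	1800	+	8	2	CpG	CGA
chrS	1801	-	7	3	CpG	CGT
chrS	1900	+	8	2	CpG	CGA
chrS	1901	-	7	3	CpG	CGT
chrS	2000	+	8	2	CpG	CGA
chrS	2001	-	7	3	CpG	CGT
chrS	2100	+	8	2	CpG	CGA
chrS	2101	-	7	3	CpG	CGT
chrS	2200	+	8	2	CpG	CGA
chrS	2201	-	7	3	CpG	CGT
chrS	2300	+	8	2	CpG	CGA
chrS	2301	-	7	3	CpG	CGT
chrS	2400	+	8	2	CpG	CGA
chrS	2401	-	7	3	CpG	CGT
chrS	2500	+	8	2	CpG	CGA
chrS	2501	-	7	3	CpG	CGT
chrS	2600	+	8	2	CpG	CGA
chrS	2601	-	7	3	CpG	CGT
chrS	2700	+	8	2	CpG	CGA
chrS	2701	-	7	3	CpG	CGT
chrS	2800	+	8	2	CpG	CGA
chrS	2801	-	7	3	CpG	CGT
chrS	2900	+	8	2	CpG	CGA
chrS	2901	-	7	3	CpG	CGT
chrS	3000	+	8	2	CpG	CGA
chrS	3001	-	7	3	CpG	CGT
chrS	3100	+	5	5	CpG	CGA
chrS	3101	-	5	5	CpG	CGT
chrS	3200	+	20	5	CpG	CGA
chrS	3201	-	20	5	CpG	CGT
chrS	3300	+	6	5	CpG	CGA
chrS	3301	-	5	5	CpG	CGT
chrS	3400	+	8	2	CpG	CGA
chrS	3401	-	7	3	CpG	CGT
chrS	3500	+	8	2	CpG	CGA
chrS	3501	-	7	3	CpG	CGT
chrS	3600	+	10	0	CpG	CGA
chrS	3601	-	0	10	CpG	CGT
chrS	3700	+	8	2	CpG	CGA
chrS	3701	-	7	3	CpG	CGT
chrS	3800	+	8	2	CpG	CGA
chrS	3801	-	7	3	CpG	CGT
chrS	3900	+	8	2	CpG	CGA
chrS	3901	-	7	3	CpG	CGT
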