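locus	group	position_cM
S1.01	1	0
S1.02	1	5.8
S1.03	1	11.6
S1.04	1	17.5
S1.05	1	23.3
S1.06	1	29.1
S1.07	1	34.9
S1.08	1	40.7
S1.09	1	46.5
S1.10	1	52.4
S1.11	1	58.2
S1.12	1	64
S1.13	1	69.8
S1.14	1	75.6
S1.15	1	81.5
S1.16	1	87.3
S1.17	1	93.1
S1.18	1	98.9
S1.19	1	104.7
S1.20	1	110.5
S1.21	1	116.4
S1.22	1	122.2
S1.23	1	128
S2.01	2	0
S2.02	2	7.4
S2.03	2	14.9
S2.04	2	22.3
S2.05	2	29.7
S2.06	2	37.1
S2.07	2	44.6
S2.08	2	52
S2.09	2	59.4
S2.10	2	66.9
S2.11	2	74.3
S2.12	2	81.7
S2.13	2	89.1
S2.14	2	96.6
S2.15	2	104
S2.16	2	111.4
S2.17	2	118.9
S2.18	2	126.3
S2.19	2	133.7
S2.20	2	141.1
S2.21	2	148.6
S2.22	2	156
S2.23	2	163.4
S2.24	2	170.9
S2.25	2	178.3
S2.26	2	185.7
S2.27	2	193.1
S2.28	2	200.6
S2.29	2	208
S3.01	3	0
S3.02	3	7.2
S3.03	3	14.4
S3.04	3	21.6
S3.05	3	28.8
S3.06	3	36
S3.07	3	43.3
S3.08	3	50.5
S3.09	3	57.7
S3.10	3	64.9
S3.11	3	72.1
S3.12	3	79.3
S3.13	3	86.5
S3.14	3	93.7
S3.15	3	100.9
S3.16	3	108.1
S3.17	3	115.4
S3.18	3	122.6
S3.19	3	129.8
S3.20	3	137
S3.21	3	144.2
S3.22	3	151.4
S4.01	4	0
S4.02	4	5.8
S4.03	4	11.7
S4.04	4	17.5
S4.05	4	23.3
S4.06	4	29.2
S4.07	4	35
S4.08	4	40.8
S4.09	4	46.6
S4.10	4	52.5
S4.11	4	58.3
S4.12	4	64.1
S4.13	4	70
S4.14	4	75.8
S5.01	5	0
S5.02	5	7.9
S5.03	5	15.8
S5.04	5	23.7
S5.05	5	31.6
S5.06	5	39.6
S5.07	5	47.5
S5.08	5	55.4
S5.09	5	63.3
S5.10	5	71.2
S5.11	5	79.1
S5.12	5	87
S5.13	5	94.9
S5.14	5	102.8
S5.15	5	110.7
S5.16	5	118.7
S5.17	5	126.6
S5.18	5	134.5
S5.19	5	142.4
S5.20	5	150.3
S5.21	5	158.2
S5.22	5	166.1
S5.23	5	174
S5.24	5	181.9
S5.25	5	189.8
S5.26	5	197.8
S5.27	5	205.7
S5.28	5	213.6
S5.29	5	221.5
S5.30	5	229.4
S6.01	6	0
S6.02	6	5.3
S6.03	6	10.6
S6.04	6	15.9
S6.05	6	21.2
S6.06	6	26.6
S6.07	6	31.9
S6.08	6	37.2
S6.09	6	42.5
S6.10	6	47.8
S6.11	6	53.1
S6.12	6	58.4
S6.13	6	63.8
S6.14	6	69.1
S6.15	6	74.4
S6.16	6	79.7
S6.17	6	85
S7.01	7	0
S7.02	7	5.6
S7.03	7	11.2
S7.04	7	16.8
S7.05	7	22.4
S7.06	7	28
S7.07	7	33.6
S7.08	7	39.2
S7.09	7	44.8
S7.10	7	50.4
S7.11	7	56
S7.12	7	61.6
S7.13	7	67.2
S7.14	7	72.8
S7.15	7	78.4
S7.16	7	84
S7.17	7	89.6
S7.18	7	95.2
S7.19	7	100.8
S7.20	7	106.4
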