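measure	state	m_high	sd_high	n_high	m_low	sd_low	n_low	variant
lsas_total	NA	82.170	12.702	23	27.830	12.282	18	pooled
lsas_fear	NA	41.610	8.419	23	13.110	6.579	18	pooled
lsas_avoidance	NA	40.570	9.811	23	14.720	8.804	18	pooled
duration_ms	A	67.810	11.770	23	71.450	16.890	18	pooled
duration_ms	B	68.500	8.080	23	70.210	20.080	18	pooled
duration_ms	C	83.640	13.560	23	62.230	10.170	18	pooled
duration_ms	D	81.880	12.190	23	109.670	35.360	18	welch
occurrence_hz	A	4.920	0.870	23	4.850	1.250	18	pooled
occurrence_hz	B	5.280	0.790	23	4.610	1.180	18	pooled
occurrence_hz	C	5.670	1.010	23	3.440	1.210	18	pooled
occurrence_hz	D	5.600	0.950	23	5.840	1.200	18	pooled
coverage_pct	A	20.550	7.010	23	22.480	10.230	18	pooled
coverage_pct	B	22.040	5.640	23	20.920	11.120	18	pooled
coverage_pct	C	29.100	9.370	23	13.200	6.230	18	pooled
coverage_pct	D	28.310	9.240	23	43.400	18.590	18	welch
gev	NA	67.740	5.940	23	58.220	7.790	18	pooled
transition	A->B	0.080	0.015	23	0.100	0.047	18	welch
transition	A->C	0.079	0.028	23	0.040	0.019	18	pooled
transition	A->D	0.071	0.025	23	0.115	0.026	18	pooled
transition	B->A	0.075	0.018	23	0.097	0.052	18	welch
transition	B->C	0.049	0.020	23	0.087	0.035	18	pooled
transition	B->D	0.087	0.035	23	0.099	0.043	18	pooled
transition	C->A	0.079	0.031	23	0.037	0.019	18	pooled
transition	C->B	0.082	0.023	23	0.049	0.021	18	pooled
transition	C->D	0.103	0.023	23	0.100	0.070	18	welch
transition	D->A	0.075	0.025	23	0.121	0.032	18	pooled
transition	D->B	0.084	0.028	23	0.096	0.040	18	pooled
transition	D->C	0.102	0.021	23	0.096	0.065	18	welch
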