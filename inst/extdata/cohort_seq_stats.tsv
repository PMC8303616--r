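sample_id	sex	lake	sequenced_reads	aligned_pct	high_quality_pct	depth
1	female	Okoboji	203824613	86.34	96.85	16.23
2	female	Okoboji	315700163	86.16	96.78	24.93
3	female	Okoboji	306850333	86.04	96.99	24.34
4	male	Okoboji	99981043	87.30	96.22	8.26
5	male	Okoboji	150029226	86.38	96.75	12.12
6	male	Okoboji	538733400	87.32	96.44	41.53
7	female	Big Spirit	438773328	86.29	95.68	49.98
8	female	Big Spirit	538733400	85.62	95.29	47.41
9	female	Big Spirit	510088829	85.62	94.77	47.41
10	male	Big Spirit	157555467	86.76	96.56	14.34
11	male	Big Spirit	140430988	86.73	96.41	12.81
12	male	Big Spirit	177235006	85.92	96.56	15.80
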