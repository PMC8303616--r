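sample_id	sex	lake	n_roh	total_kb
S1	female	Okoboji	0	0.00
S2	female	Okoboji	2	12622.20
S3	female	Okoboji	3	23042.30
S4	male	Okoboji	2	12730.70
S5	male	Okoboji	2	15358.40
S6	male	Okoboji	4	24561.20
S7	female	Big Spirit	5	36351.40
S8	female	Big Spirit	5	36499.60
S9	female	Big Spirit	7	50042.80
S10	male	Big Spirit	4	31859.10
S11	male	Big Spirit	3	21129.30
S12	male	Big Spirit	5	36699.20
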