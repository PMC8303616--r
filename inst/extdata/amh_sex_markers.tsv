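pos	female_genotype	male_genotype
12874481	GG	CG
12874504	TT	CT
12874507	CC	TC
12874514	CC	TC
12874526	CC	AC
12874527	TT	AT
12874533	CC	TC
12874566	AA	TA
12874586	GG	AG
12874588	CC	TC
12874615	AA	CA
12874618	AA	GA
12874754	CC	GC
12874758	CC	TC
12874767	GG	AG
12874789	TT	CT
12874791	AA	GA
12874806	AA	CA
12874809	TT	CT
12874836	GG	AG
12874848	GG	CG
12874854	CC	TC
12874858	CC	TC
12874860	GG	AG
12874865	TT	CT
12874882	AA	TA
12874913	TT	AT
12874914	GG	AG
12874937	CC	TC
12875043	AA	GA
12875046	CC	AC
12875056	CC	TC
12875960	AA	GA
12875988	TT	GT
12875992	TT	GT
12876003	CC	TC
12876008	CC	TC
12876021	TT	AT
12876022	CC	TC
12876024	CC	AC
12876026	TT	AT
12876049	CC	AC
12876056	TT	AT
12876057	CC	TC
12876063	CC	GC
12876066	AA	TA
12876083	TT	GT
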