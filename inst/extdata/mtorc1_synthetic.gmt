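MTORC1_SIGNALING	synthetic stand-in mTORC1 signaling set (39 symbols); supply a curated GMT for real analyses	MTOR	RPTOR	MLST8	AKT1S1	DEPTOR	RHEB	RPS6KB1	RPS6KB2	RPS6	EIF4EBP1	EIF4E	EIF4B	TSC1	TSC2	TBC1D7	RRAGA	RRAGB	RRAGC	RRAGD	LAMTOR1	LAMTOR2	LAMTOR3	LAMTOR4	LAMTOR5	FLCN	FNIP1	FNIP2	SLC38A9	SESN2	CASTOR1	DDIT4	AKT1	PIK3CA	PDPK1	PTEN	ULK1	TFEB	SREBF1	HIF1A
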