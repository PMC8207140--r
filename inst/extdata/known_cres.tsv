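name	consensus	source	description
IDE1	CATGC	known-Fe	Fe-deficiency-responsive element 1 core
IDE2	CAMGYHH	known-Fe	Fe-deficiency-responsive element 2 (CA[A/C]G[TC][T/C/A][T/C/A])
IDRS	CCTCCAC	known-Fe	Fe-dependent regulatory sequence
OsIRO2_binding	CACGTGG	known-Fe	bHLH OsIRO2 binding site
IDEF1_binding	CATGCATG	known-Fe	IDEF1 binding site
Wbox_WRKY	TTGACC	PLACE-like	W-box bound by WRKY transcription factors
DCEp1_FAM1	AGCTAGCT	PLACE-like	Downstream core element in plant 1 / FAM1
DCEp2	ATCGATCG	PLACE-like	Downstream core element in plant 2
EECCRCAH1	GANTTNC	PLACE-like	Enhancer element of Chlamydomonas CAH1
GCGC_box	GCGCGCCA	PLACE-like	Zinc finger binding GCGC box
bZIP_bHLH	CTACGTGC	PLACE-like	bZIP/bHLH binding G-box-like motif
Myb_like	CACCAACC	PLACE-like	Myb binding-like motif
CGACACGC_novel	CGACACGC	PLACE-like	Fe excess-enriched candidate
ATAATGGC_novel	ATAATGGC	PLACE-like	Zn deficiency-responsive candidate (TSS-downstream)
GCWGCWGC_novel	GCWGCWGC	PLACE-like	Degenerate GCWGCWGC family
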