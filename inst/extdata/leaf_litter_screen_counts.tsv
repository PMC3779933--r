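library	clones_screened	AZCL-HE-cellulose	4-MUB-beta-D-cellobiose	PNP-beta-D-glucopyranoside	AZCL-xylan	4-MUB-beta-D-xyloside	starch-azure	4-MUB-alpha-D-glucoside	chitin-azure	4-MUB-beta-N-acetylglucosamine	L-DOPA	syringaldazine	BCIP	skim-milk
Dec10_01XX	21755	0	12	6	5	24	2	4	0	8	0	0	9	0
Dec10_08XX	18540	1	23	11	5	19	1	4	0	16	0	0	10	1
Feb11_01XX	10830	0	13	9	7	20	2	0	0	7	0	0	4	1
Feb11_08XX	15105	0	9	6	6	11	0	2	0	15	0	0	3	0
Feb11_16XN	26818	4	31	14	6	31	1	3	0	19	0	0	7	0
Mar12_01XX	25080	0	6	4	2	14	1	0	0	2	0	0	0	0
Mar12_08XX	25080	0	6	1	1	8	0	0	0	4	0	0	1	2
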