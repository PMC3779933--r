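family	substrates
GH1	PNP-beta-D-glucopyranoside,4-MUB-beta-D-cellobiose,4-MUB-beta-D-xyloside
GH3	PNP-beta-D-glucopyranoside,4-MUB-beta-D-cellobiose,4-MUB-beta-D-xyloside
GH9	AZCL-HE-cellulose,4-MUB-beta-D-cellobiose
GH10	AZCL-xylan,4-MUB-beta-D-cellobiose
GH13	starch-azure,4-MUB-alpha-D-glucoside
GH15	starch-azure,4-MUB-alpha-D-glucoside
GH31	starch-azure,4-MUB-alpha-D-glucoside
GH97	starch-azure,4-MUB-alpha-D-glucoside
GH2	4-MUB-beta-N-acetylglucosamine
GH20	4-MUB-beta-N-acetylglucosamine
GH84	4-MUB-beta-N-acetylglucosamine
GH109	4-MUB-beta-N-acetylglucosamine
phosphatase	BCIP-acid,BCIP-alkaline
protease	skim-milk
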