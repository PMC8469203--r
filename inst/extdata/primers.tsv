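cluster	fwd	rev	expected_len
A	MCTGGGYATYCACACCGAG	GGTGGGCGATGGAGATAA	574
B	GGKCCBATHGARRTTGCAGA	TKTCGTCMASCCABTCATAC	679
C	GBGACTGGSTRGATTAYG	TCVACRTACATYTCSGTGTG	682
D	TGGAAYTCMTGGCATATGTC	VGMRTTGTTRATGGAMATAAA	726
E	TGHAGSABHTSWTTTTACATGGA	SSCTTTGCAATGTCAACAAA	558
F	AAATATGCCTCGHTGCYTWG	ARRTARGCACCYAWAACGAAATC	585
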