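family_size,poverty_line_usd,year
1,8590,2001
2,11610,2001
3,14630,2001
4,17650,2001
5,20670,2001
6,23690,2001
7,26710,2001
8,29730,2001
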