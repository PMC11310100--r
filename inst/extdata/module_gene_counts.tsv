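scale	module	n_genes
scale1	black	153
scale1	blue	1163
scale1	brown	427
scale1	cyan	45
scale1	green	261
scale1	greenyellow	77
scale1	gray	708
scale1	lightcyan	41
scale1	magenta	108
scale1	midnightblue	44
scale1	pink	125
scale1	purple	99
scale1	red	190
scale1	salmon	45
scale1	tan	75
scale1	turquoise	1202
scale1	yellow	330
scale1	All	5093
scale2	black	38
scale2	blue	1251
scale2	brown	744
scale2	green	324
scale2	gray	328
scale2	red	149
scale2	turquoise	1877
scale2	yellow	382
scale2	All	5093
scale3	blue	1039
scale3	brown	254
scale3	green	135
scale3	gray	1284
scale3	red	74
scale3	turquoise	2124
scale3	yellow	183
scale3	All	5093
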