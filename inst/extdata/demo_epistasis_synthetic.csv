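"snp001","snp002","snp003","snp004","snp005","snp006","snp007","snp008","snp009","snp010","phenotype"
1,0,0,1,0,2,0,0,0,0,1
0,1,1,1,0,1,0,0,0,0,1
0,0,1,1,1,2,0,0,1,0,1
0,1,0,0,0,1,0,1,1,0,1
0,0,1,0,1,1,0,1,0,1,1
0,1,1,1,0,1,0,1,0,0,1
1,0,1,2,1,1,1,1,1,0,1
0,2,1,1,1,1,0,2,1,1,1
1,0,2,0,1,1,0,2,0,0,1
0,2,0,1,2,1,1,2,1,0,1
1,1,1,1,1,2,0,1,0,0,1
0,0,2,1,0,1,0,1,1,0,1
0,1,0,0,2,1,0,0,0,1,1
0,1,0,0,0,2,0,1,1,1,1
0,2,2,0,1,0,0,0,2,0,1
1,0,0,0,0,1,0,1,0,0,1
0,2,1,1,1,1,0,1,1,1,1
1,0,2,0,2,2,0,0,0,0,1
1,0,2,1,0,0,1,1,2,1,1
1,0,1,2,1,0,0,1,0,2,1
1,0,1,0,0,2,0,0,1,0,1
0,1,1,0,0,1,0,1,1,0,1
0,2,2,2,1,1,1,1,0,0,1
2,0,0,0,0,2,0,0,0,1,1
1,0,0,0,0,1,0,0,2,0,1
0,1,1,0,2,2,0,0,1,0,1
2,0,0,1,1,0,0,1,0,0,1
1,0,2,1,2,0,0,0,0,0,1
1,0,2,0,1,1,0,1,1,1,1
0,1,2,0,1,0,0,0,2,0,1
1,0,2,0,0,1,0,2,0,0,1
1,0,1,0,0,2,0,0,0,1,1
2,1,0,0,1,1,0,2,0,0,1
0,1,0,1,1,1,0,0,0,0,1
0,1,2,1,1,1,0,1,1,0,1
1,0,1,1,1,1,0,2,1,0,1
1,1,1,0,1,1,0,1,1,0,1
1,0,0,0,0,0,0,0,1,0,1
0,1,1,1,1,1,0,1,0,0,1
0,2,0,2,1,1,0,1,2,0,1
0,2,0,0,1,1,0,1,2,0,1
0,1,0,0,0,2,0,1,1,1,1
0,1,0,0,0,0,0,2,1,0,1
0,2,2,0,0,1,0,1,0,0,1
0,1,0,1,1,1,0,1,1,0,1
0,1,0,1,1,1,0,0,0,0,1
1,0,1,1,0,0,0,2,1,0,1
0,1,0,0,1,1,0,2,1,0,1
0,1,0,1,1,2,0,1,0,1,1
1,0,1,0,0,1,0,2,0,0,1
0,0,0,1,0,1,0,1,0,0,1
0,1,0,0,0,1,0,1,2,1,1
0,1,1,1,2,0,0,1,1,0,1
0,0,0,0,1,1,1,2,1,0,1
0,0,0,0,2,1,2,1,1,0,1
1,0,0,1,1,1,0,1,1,0,1
1,0,0,0,0,0,1,2,0,0,1
0,1,1,0,0,1,0,2,1,0,1
1,0,0,0,0,1,1,0,0,0,1
1,0,1,1,1,1,0,2,1,0,1
0,1,0,0,1,2,0,0,0,0,1
0,1,0,0,0,2,0,0,2,0,1
0,1,2,1,2,0,0,2,1,0,1
1,0,0,1,1,1,0,2,0,0,1
2,0,1,1,0,0,0,1,0,1,1
0,2,1,0,0,2,0,0,0,0,1
0,0,0,0,0,1,1,0,0,0,1
1,0,1,0,1,0,0,1,1,0,1
1,0,1,0,1,2,1,0,2,1,1
0,1,0,1,0,2,0,1,1,0,1
1,0,1,1,2,0,0,0,0,0,1
0,1,1,0,0,1,0,1,0,1,1
0,1,1,2,0,1,1,1,0,0,1
1,0,1,0,1,1,0,2,1,0,1
0,0,0,0,0,1,0,0,1,0,1
1,0,0,1,0,2,1,1,0,1,1
1,0,1,0,1,2,0,1,1,0,1
0,1,0,0,1,2,0,1,1,1,1
1,0,0,0,1,2,0,0,1,1,1
1,0,2,1,1,0,0,0,0,0,1
1,0,1,0,0,2,0,1,0,0,1
0,1,0,2,0,1,2,2,0,0,1
1,0,1,0,0,0,0,1,0,0,1
0,0,2,0,1,1,1,1,0,0,1
0,1,1,1,0,1,0,1,1,0,1
2,1,0,1,0,2,1,0,0,0,1
1,0,0,0,0,2,0,0,0,0,1
1,0,2,0,1,1,0,1,1,0,1
0,2,2,2,0,0,0,0,1,2,1
0,1,1,1,0,1,1,0,0,0,1
0,2,0,0,0,1,0,1,0,0,1
0,1,0,0,0,2,0,2,1,0,1
1,0,0,1,1,1,1,2,0,0,1
0,0,0,1,1,1,0,2,1,1,1
1,0,2,0,0,2,0,1,0,0,1
0,0,1,1,0,1,1,1,0,0,1
0,1,1,0,1,0,1,1,2,1,1
2,1,0,0,0,1,0,0,0,0,1
0,1,0,0,0,1,0,1,1,1,1
1,0,0,0,2,0,0,1,0,0,1
0,1,0,0,1,1,1,1,2,1,1
1,0,1,0,1,2,1,1,1,0,1
0,1,1,1,1,2,0,0,2,0,1
1,0,1,1,1,1,0,0,2,1,1
2,0,0,0,1,0,0,0,1,0,1
1,0,0,1,2,1,0,1,0,0,1
1,0,0,0,0,0,0,1,0,0,1
1,0,0,1,0,1,0,0,1,0,1
2,0,1,0,0,2,0,0,1,0,1
1,0,0,0,1,0,1,2,0,0,1
0,1,1,1,0,0,0,1,2,0,1
2,0,1,0,0,0,0,2,1,0,1
1,0,2,0,1,1,0,1,0,1,1
0,1,0,1,0,1,1,1,1,0,1
0,2,0,2,1,1,1,2,0,0,1
0,2,1,0,1,0,0,0,0,0,1
1,0,2,0,1,1,1,0,0,0,1
0,1,1,0,0,2,0,1,1,0,1
1,0,1,1,0,1,1,2,2,1,1
1,1,0,1,1,1,0,1,0,0,1
1,0,2,1,1,1,0,2,0,2,1
2,0,0,0,1,0,0,1,0,1,1
1,0,1,0,0,0,0,2,1,0,1
0,0,0,1,1,1,0,1,0,0,1
1,0,0,1,0,1,0,1,1,1,1
0,1,0,1,1,2,0,0,2,0,1
2,0,2,0,0,1,0,0,2,0,1
1,1,1,1,1,1,0,1,0,0,1
1,2,2,0,1,1,0,1,0,0,1
0,1,0,0,1,1,0,1,1,1,1
1,0,0,0,1,1,0,0,1,0,1
1,0,1,2,1,0,0,2,1,0,1
0,1,0,0,0,1,0,1,0,1,1
0,0,2,0,1,1,0,1,0,1,1
0,1,1,0,1,1,0,1,1,1,1
0,0,0,0,1,1,0,1,1,2,1
1,0,0,1,0,1,0,1,1,0,1
1,0,0,0,1,1,0,1,0,1,1
0,1,0,0,2,1,0,0,1,0,1
0,2,0,0,1,1,0,0,2,0,1
0,1,1,1,0,2,1,2,0,0,1
1,0,0,0,2,1,1,0,1,1,1
0,1,0,1,2,0,0,1,0,0,1
0,1,0,0,1,1,0,0,1,0,1
1,2,1,0,2,1,0,1,1,0,1
0,1,0,0,0,1,0,2,0,0,1
1,0,1,0,1,2,0,1,0,1,1
0,1,1,2,0,0,0,1,2,0,1
0,1,0,0,0,1,0,0,1,0,1
0,1,0,0,0,1,0,1,0,0,1
0,1,0,1,0,1,0,0,1,0,0
2,1,2,1,1,1,0,1,1,0,0
0,0,1,1,0,0,0,0,2,1,0
1,1,0,0,1,2,0,0,0,0,0
0,1,1,0,1,2,0,2,0,0,0
0,0,1,1,1,0,0,1,1,1,0
0,0,1,2,0,2,0,1,0,1,0
1,0,1,0,0,2,0,1,1,0,0
0,0,0,0,1,1,0,0,2,0,0
0,0,0,2,0,0,0,1,0,2,0
1,1,1,0,2,1,0,0,2,0,0
2,0,0,1,2,1,0,0,1,1,0
0,0,1,0,2,1,0,0,0,0,0
1,1,0,0,1,0,0,0,0,2,0
1,1,1,0,1,1,0,2,1,0,0
0,0,1,1,1,0,0,1,0,0,0
1,0,1,0,0,2,0,1,1,0,0
1,0,0,0,1,1,1,1,1,0,0
0,1,0,1,1,1,0,1,2,1,0
2,0,1,1,0,1,0,1,0,1,0
1,1,0,2,0,2,1,0,0,0,0
0,1,0,0,1,1,0,1,0,0,0
1,1,0,2,0,1,0,1,2,0,0
0,1,0,1,1,1,1,0,0,0,0
1,0,1,0,0,2,0,0,1,0,0
0,1,2,1,0,2,1,1,1,1,0
0,0,1,0,0,1,0,1,0,1,0
1,1,0,0,1,2,0,1,2,0,0
1,0,0,1,2,1,0,0,1,0,0
0,0,1,1,1,2,1,0,0,0,0
2,1,1,0,0,1,0,1,2,0,0
0,1,2,1,2,1,1,2,0,2,0
1,1,2,1,0,1,0,1,0,0,0
0,0,1,0,0,1,1,1,2,0,0
2,2,0,0,0,0,0,1,0,1,0
1,1,0,0,1,2,0,1,1,0,0
1,1,0,1,1,2,0,1,1,0,0
1,1,1,0,1,2,1,1,0,0,0
0,0,0,0,1,1,1,1,0,0,0
0,0,0,0,0,1,0,0,1,0,0
0,0,0,0,0,0,1,0,0,1,0
0,0,2,2,0,1,0,1,0,1,0
0,0,1,0,2,1,2,2,0,0,0
0,0,0,1,0,2,0,1,1,1,0
0,0,1,0,1,0,0,1,1,0,0
1,0,0,1,0,1,1,1,0,0,0
1,0,1,1,1,2,0,0,0,0,0
0,2,1,0,1,1,0,1,2,2,0
2,1,0,0,0,0,0,1,0,1,0
1,2,0,1,1,1,0,1,0,0,0
0,0,0,0,1,0,0,0,1,0,0
1,1,1,0,0,1,0,1,0,1,0
0,0,1,0,1,1,0,1,1,1,0
2,0,0,1,1,1,1,1,1,1,0
0,0,0,0,1,1,0,2,2,0,0
1,0,1,0,2,1,0,1,1,1,0
0,1,1,0,1,1,0,1,2,0,0
0,0,0,1,1,0,0,0,0,1,0
2,0,0,0,1,0,0,1,1,0,0
1,1,1,1,0,0,0,1,0,0,0
0,2,2,0,0,1,0,0,0,1,0
0,1,1,1,2,1,0,0,1,0,0
1,0,0,0,0,0,0,1,2,1,0
0,2,1,0,2,1,0,0,1,0,0
1,0,2,0,1,0,0,0,0,0,0
0,1,0,1,1,0,0,1,1,1,0
1,1,0,0,0,1,0,2,1,1,0
0,0,1,1,1,0,0,1,1,0,0
0,0,0,0,1,1,0,0,1,1,0
0,0,1,1,1,2,0,1,0,0,0
1,0,1,0,1,1,0,0,0,0,0
0,2,0,0,0,1,0,1,1,0,0
1,0,0,1,2,0,0,1,0,1,0
0,0,1,0,0,1,1,0,0,0,0
2,0,0,0,1,1,1,1,2,0,0
1,0,0,0,0,2,0,1,0,1,0
1,0,1,0,0,1,1,1,1,0,0
0,1,0,0,0,0,0,1,1,0,0
1,0,1,0,1,2,0,1,0,0,0
0,0,0,1,1,0,0,0,1,0,0
0,0,0,1,0,0,0,0,0,0,0
1,2,0,0,1,2,1,1,2,0,0
0,1,0,0,0,1,0,0,1,0,0
1,1,1,2,1,1,0,1,1,1,0
2,1,0,1,2,0,0,1,0,0,0
0,1,1,0,0,1,0,1,0,0,0
0,0,0,1,0,1,0,2,1,1,0
1,1,1,0,1,1,0,1,1,0,0
2,1,1,0,0,1,0,0,0,0,0
0,1,0,1,0,1,1,1,1,0,0
0,0,0,1,2,0,0,0,0,0,0
0,1,0,0,2,2,1,1,1,0,0
0,1,0,0,1,2,1,1,0,1,0
0,0,1,1,1,2,0,1,1,1,0
0,0,2,0,2,1,1,0,0,0,0
0,1,1,0,1,2,0,2,1,0,0
1,1,0,1,0,2,0,1,0,0,0
0,0,1,1,2,2,0,2,1,0,0
1,1,0,1,1,1,0,1,1,0,0
1,0,0,1,1,1,0,1,0,1,0
0,0,0,1,0,1,0,1,0,0,0
0,0,0,2,1,1,0,1,1,0,0
1,0,0,1,1,2,0,0,0,0,0
0,0,0,1,0,2,0,1,2,0,0
0,1,0,0,1,0,0,0,1,1,0
0,1,2,1,1,1,0,0,0,0,0
0,1,1,1,2,0,0,1,1,0,0
1,1,0,0,1,0,0,1,0,0,0
0,0,1,0,0,1,0,1,0,0,0
0,0,0,1,0,1,0,1,1,0,0
0,0,0,0,0,1,0,1,1,0,0
1,0,1,1,0,1,0,1,1,0,0
1,1,0,2,0,2,0,0,0,0,0
0,0,1,0,0,2,0,2,0,0,0
1,0,1,0,1,1,0,1,1,1,0
1,0,0,0,1,0,1,1,2,0,0
0,0,1,1,0,0,0,2,1,0,0
1,2,0,0,2,2,0,2,1,0,0
1,2,1,0,1,0,0,0,0,0,0
0,0,2,0,2,1,0,1,1,1,0
0,0,0,1,0,1,1,1,1,2,0
0,0,1,0,0,1,0,1,1,1,0
0,0,1,1,0,0,2,1,0,0,0
1,1,0,2,1,1,1,2,1,2,0
1,0,1,1,1,0,0,1,0,0,0
1,0,2,0,1,2,0,0,1,0,0
0,0,0,0,1,1,1,2,1,0,0
0,1,1,0,0,1,0,1,1,1,0
1,2,0,1,0,2,0,2,0,0,0
1,1,0,1,1,1,1,0,2,0,0
1,0,0,0,1,1,0,1,2,0,0
0,0,0,0,1,0,0,2,1,0,0
1,0,1,0,1,0,0,1,0,0,0
0,0,2,0,1,1,0,0,0,0,0
0,1,0,1,1,0,1,1,2,0,0
1,2,1,0,2,1,1,1,0,0,0
1,2,2,0,1,1,0,1,2,1,0
1,1,1,1,0,2,1,1,0,0,0
0,0,0,0,0,2,0,1,1,1,0
1,1,0,0,1,1,0,1,1,0,0
2,0,0,1,1,1,0,0,0,0,0
1,2,0,0,1,1,0,0,0,0,0
1,1,0,0,1,1,1,0,0,0,0
1,0,1,1,2,0,0,0,1,2,0
0,1,0,0,0,1,0,1,0,0,0
1,1,1,0,0,2,0,1,0,0,0
1,1,0,1,0,2,0,2,1,0,0
2,0,0,0,0,1,0,1,1,1,0
0,0,1,1,0,1,0,1,0,1,0
0,0,2,1,0,2,1,2,0,0,0
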