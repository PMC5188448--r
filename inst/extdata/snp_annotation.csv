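"snp_id","gene_label","allele_a","allele_b","risk_allele"
"rs7903146","TCF7L2","C","T","T"
"rs12899811","PRC1","A","G","G"
"rs11634397","ZFAND6","G","A","G"
"rs11257655","CDC123_CAMK1D","C","T","T"
"rs163184","KCNQ1","T","G","G"
"rs6798189","ADCY5","A","G","G"
"rs4402960","IGF2BP2","G","T","T"
"rs3802177","SLC30A8","G","A","G"
"rs10842994","KLHDC5","C","T","C"
"rs2261181","HMGA2","C","T","T"
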