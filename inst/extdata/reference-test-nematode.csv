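species,division,category,gene_symbol,ncbi_gene_ids,uniprot_ids,ensembl_ids,zfin_ids,flybase_ids,wormbase_ids,common_names
nematode,Core matrisome,ECM Glycoproteins,epi-1,180112,P41525,,,,WBGene00001328,epi-1
nematode,Core matrisome,ECM Glycoproteins,unc-52,181775,Q06561,,,,WBGene00006787,unc-52
nematode,Core matrisome,Collagens,emb-9,175875,P17139,,,,WBGene00001303,emb-9
nematode,Core matrisome,Collagens,let-2,183651,P17140,,,,WBGene00002287,let-2
nematode,Core matrisome,Proteoglycans,sdn-1,177306,Q18823,,,,WBGene00004749,sdn-1
nematode,Core matrisome,Proteoglycans,gpn-1,176056,Q10122,,,,WBGene00001687,gpn-1
nematode,Matrisome-associated,ECM-affiliated Proteins,lec-1,178501,P36573,,,,WBGene00002264,lec-1
nematode,Matrisome-associated,ECM-affiliated Proteins,clec-1,181706,Q9XWA9,,,,WBGene00000524,clec-1
nematode,Matrisome-associated,ECM Regulators,zmp-1,174893,Q21343,,,,WBGene00006977,zmp-1
nematode,Matrisome-associated,ECM Regulators,cpl-1,178775,Q27450,,,,WBGene00000781,cpl-1
nematode,Matrisome-associated,Secreted Factors,dbl-1,175611,Q17406,,,,WBGene00000936,dbl-1
nematode,Matrisome-associated,Secreted Factors,unc-129,177927,O16259,,,,WBGene00006818,unc-129
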