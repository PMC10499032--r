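species,division,category,gene_symbol,ncbi_gene_ids,uniprot_ids,ensembl_ids,zfin_ids,flybase_ids,wormbase_ids,common_names
human,Core matrisome,ECM Glycoproteins,FN1,2335,P02751,ENSG00000115414,,,,
human,Core matrisome,ECM Glycoproteins,LAMA1,284217,P25391,ENSG00000101680,,,,
human,Core matrisome,Collagens,COL1A1,1277,P02452,ENSG00000108821,,,,
human,Core matrisome,Collagens,COL4A1,1282,P02462,ENSG00000187498,,,,
human,Core matrisome,Proteoglycans,ACAN,176,P16112,ENSG00000157766,,,,
human,Core matrisome,Proteoglycans,BGN,633,P21810,ENSG00000182492,,,,
human,Matrisome-associated,ECM-affiliated Proteins,ANXA1,301,P04083,ENSG00000135046,,,,
human,Matrisome-associated,ECM-affiliated Proteins,LGALS1,3956,P09382,ENSG00000100097,,,,
human,Matrisome-associated,ECM Regulators,MMP2,4313,P08253,ENSG00000087245,,,,
human,Matrisome-associated,ECM Regulators,LOX,4015,P28300,ENSG00000113083,,,,
human,Matrisome-associated,Secreted Factors,VEGFA,7422,P15692,ENSG00000112715,,,,
human,Matrisome-associated,Secreted Factors,TGFB1,7040,P01137,ENSG00000105329,,,,
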