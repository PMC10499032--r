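species,division,category,gene_symbol,ncbi_gene_ids,uniprot_ids,ensembl_ids,zfin_ids,flybase_ids,wormbase_ids,common_names
zebrafish,Core matrisome,ECM Glycoproteins,fn1a,31731,B8A5F4,,ZDB-GENE-990415-72,,,
zebrafish,Core matrisome,ECM Glycoproteins,lama1,563512,A4QNX5,,ZDB-GENE-050419-82,,,
zebrafish,Core matrisome,Collagens,col1a1a,114427,Q9W6F2,,ZDB-GENE-990415-39,,,
zebrafish,Core matrisome,Collagens,col4a1,557771,F1QHL4,,ZDB-GENE-061013-232,,,
zebrafish,Core matrisome,Proteoglycans,acana,561383,E7F1I8,,ZDB-GENE-081104-327,,,
zebrafish,Core matrisome,Proteoglycans,bgnb,100003810,E7EZD2,,ZDB-GENE-080225-9,,,
zebrafish,Matrisome-associated,ECM-affiliated Proteins,anxa1a,445203,Q6P0S5,,ZDB-GENE-040718-147,,,
zebrafish,Matrisome-associated,ECM-affiliated Proteins,lgals1l1,30662,Q9I9K4,,ZDB-GENE-991019-4,,,
zebrafish,Matrisome-associated,ECM Regulators,mmp2,337250,Q9I9R8,,ZDB-GENE-030318-3,,,
zebrafish,Matrisome-associated,ECM Regulators,loxa,554111,A4IG47,,ZDB-GENE-051023-6,,,
zebrafish,Matrisome-associated,Secreted Factors,vegfaa,30682,O73682,,ZDB-GENE-990415-273,,,
zebrafish,Matrisome-associated,Secreted Factors,tgfb1a,562762,Q6IWL4,,ZDB-GENE-040801-203,,,
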