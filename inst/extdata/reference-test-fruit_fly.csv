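species,division,category,gene_symbol,ncbi_gene_ids,uniprot_ids,ensembl_ids,zfin_ids,flybase_ids,wormbase_ids,common_names
fruit_fly,Core matrisome,ECM Glycoproteins,LanA,43367,P10723,,,FBgn0002526,,
fruit_fly,Core matrisome,ECM Glycoproteins,Tig,36924,Q9VMA0,,,FBgn0011722,,
fruit_fly,Core matrisome,Collagens,Cg25C,33320,P08120,,,FBgn0000299,,
fruit_fly,Core matrisome,Collagens,vkg,35693,Q9VQ99,,,FBgn0016075,,
fruit_fly,Core matrisome,Proteoglycans,trol,45022,Q9VZY4,,,FBgn0284408,,
fruit_fly,Core matrisome,Proteoglycans,Sdc,37288,P49415,,,FBgn0010415,,
fruit_fly,Matrisome-associated,ECM-affiliated Proteins,Glt,33431,P15215,,,FBgn0001114,,
fruit_fly,Matrisome-associated,ECM-affiliated Proteins,Hml,39081,Q9VDV1,,,FBgn0029167,,
fruit_fly,Matrisome-associated,ECM Regulators,Mmp1,35159,Q9VZV1,,,FBgn0035049,,
fruit_fly,Matrisome-associated,ECM Regulators,Mmp2,36108,A0AQF3,,,FBgn0033438,,
fruit_fly,Matrisome-associated,Secreted Factors,dpp,33432,P07713,,,FBgn0000490,,
fruit_fly,Matrisome-associated,Secreted Factors,spz,43847,P48607,,,FBgn0003495,,
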