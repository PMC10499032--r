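Accession,Annotated Matrisome Division,Annotated Matrisome Category,Annotated Gene Ontology: Cellular Component,Total Spectra,Molecular Weight,Identification Probability,Note
,Non-matrisome,Non-matrisome,,6,20.0,91.0%,blank id
4313,Matrisome-associated,ECM Regulators,,9,73.9,98.0%,ncbi mmp2
aardvark,Non-matrisome,Non-matrisome,,1,10.0,90.0%,decoy lower
ALB,Non-matrisome,Non-matrisome,extracellular region;blood microparticle,30,69.3,97.2%,"has, comma"
Bgn,Core matrisome,Proteoglycans,,4,41.7,92.3%,title case
col1a1,Core matrisome,Collagens,collagen type I trimer;extracellular matrix,3,139.0,98.5%,lowercase symbol
ENSG00000112715.4,Matrisome-associated,Secreted Factors,,2,27.0,95.5%,ensembl version
P02452-2;JUNK1,Core matrisome,Collagens,,5,138.9,96.0%,isoform multi
P02751,Core matrisome,ECM Glycoproteins,extracellular matrix,12,262.6,99.9%,uniprot fn1
ZZZ999,Non-matrisome,Non-matrisome,,7,88.1,99.0%,plain
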