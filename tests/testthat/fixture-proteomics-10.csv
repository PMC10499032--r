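Accession,Total Spectra,Molecular Weight,Identification Probability,Note
ZZZ999,7,88.1,99.0%,plain
col1a1,3,139.0,98.5%,lowercase symbol
P02751,12,262.6,99.9%,uniprot fn1
ALB,30,69.3,97.2%,"has, comma"
P02452-2;JUNK1,5,138.9,96.0%,isoform multi
ENSG00000112715.4,2,27.0,95.5%,ensembl version
4313,9,73.9,98.0%,ncbi mmp2
aardvark,1,10.0,90.0%,decoy lower
Bgn,4,41.7,92.3%,title case
,6,20.0,91.0%,blank id
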