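identifier	term
ALB	extracellular region
ALB	blood microparticle
COL1A1	collagen type I trimer
COL1A1	extracellular matrix
P02751	extracellular matrix
ACTB	cytoplasm
GAPDH	cytosol
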