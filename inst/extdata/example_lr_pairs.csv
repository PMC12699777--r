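ligand,receptor,affinity,prior_confident
Psap,Gpr37l1,1.0,true
Ptn,Ptprz1,0.9,true
Ptn,Ncl,0.7,true
Ptn,Sdc3,0.6,true
Ncam1,Ncam1,0.8,true
Fgf1,Fgfr1,0.9,true
Sdc4,Fgfr1,0.5,false
Nlgn3,Nrxn1,0.8,true
Cadm3,Cadm3,0.7,true
Nectin1,Nectin3,0.6,false
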