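# Drosophila DIP/Dpr interaction-specificity subgroups (seven per side)
# and the cognate subfamily pairing of the interactome.
[dip_subgroups]
DIP-theta/eta/iota = DIP-theta,DIP-eta,DIP-iota
DIP-kappa = DIP-kappa
DIP-alpha = DIP-alpha
DIP-beta/lambda = DIP-beta,DIP-lambda
DIP-gamma = DIP-gamma
DIP-delta = DIP-delta
DIP-epsilon/zeta = DIP-epsilon,DIP-zeta

[dpr_subgroups]
Dpr1/2/3/4/5 = Dpr1,Dpr2,Dpr3,Dpr4,Dpr5
Dpr7 = Dpr7
Dpr6/10 = Dpr6,Dpr10
Dpr8/9/21 = Dpr8,Dpr9,Dpr21
Dpr11/15/16/17 = Dpr11,Dpr15,Dpr16,Dpr17
Dpr12 = Dpr12
Dpr13/14/18/19/20 = Dpr13,Dpr14,Dpr18,Dpr19,Dpr20

[cognate]
DIP-theta/eta/iota	Dpr1/2/3/4/5
DIP-kappa	Dpr7
DIP-alpha	Dpr6/10
DIP-beta/lambda	Dpr8/9/21
DIP-gamma	Dpr11/15/16/17
DIP-delta	Dpr12
DIP-epsilon/zeta	Dpr13/14/18/19/20
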