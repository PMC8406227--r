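marker_id	name	kos
rubisco	RuBisCO	K01601,K01602
prk	Phosphoribulokinase	K00855
codh_acs	CO dehydrogenase / acetyl-CoA synthase complex	K00192,K00193,K00194,K00197
acs	Acetyl-CoA synthase	K01895
hbd	4-Hydroxybutyryl-CoA dehydratase	K14534
mmo	Methane monooxygenase	K10944,K10945,K10946,K16157
icl	Isocitrate lyase	K01637
mas	Malate synthase	K01638
codh_large	CODH large chain (coxL)	K03520
codh_medium	CODH medium chain (coxM)	K03519
codh_small	CODH small chain (coxS)	K03518
amo	Ammonia monooxygenase	K10944
nap	Periplasmic nitrate reductase	K02567,K02568
nar	Respiratory nitrate reductase	K00370,K00371,K00374
nir	Nitrite reductase	K00368,K15864
nor	Nitric oxide reductase	K04561,K02305
apr	Adenylylsulfate reductase	K00394,K00395
pap	Phosphoadenosine phosphosulfate reductase	K00390
dsr	Sulfite reductase (dsrAB)	K11180,K11181
hyd_nife	Periplasmic [NiFe] hydrogenase	K06281,K06282
hyd_nifese	Periplasmic [NiFeSe] hydrogenase	K00436
hyd_fefe_nadp	NADP-reducing [FeFe] hydrogenase	K00532,K00533,K00534
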