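pathway_id	name	kos
cbb	Calvin-Benson-Bassham cycle	K01601,K01602,K00855,K00927,K00134,K01623,K01803,K00615,K01807,K01100
rtca	Reductive TCA cycle	K15230,K15231,K00174,K00175,K00176,K00177
wl	Wood-Ljungdahl pathway	K00198,K05299,K15022,K01938,K01491,K00297,K15023,K14138,K00197,K00194,K00192,K00193
tca	TCA cycle	K01647,K01681,K00031,K00164,K00658,K01902,K01903,K00239,K01679,K00024
glycolysis	Glycolysis / gluconeogenesis	K00844,K01810,K00850,K01623,K01803,K00134,K00927,K15633,K01689,K00873
glyoxylate_shunt	Glyoxylate shunt	K01637,K01638
nitrate_reduction_nap	Periplasmic nitrate reduction (nap)	K02567,K02568
nitrate_reduction_nar	Respiratory nitrate reduction (nar)	K00370,K00371,K00374
nitrite_reduction	Nitrite reduction (nirK/nirS)	K00368,K15864
no_reduction	Nitric oxide reduction (norBC)	K04561,K02305
n2o_reduction	Nitrous oxide reduction (nosZ)	K00376
sulfate_reduction	Sulfate reduction (sat + aprAB)	K00958,K00394,K00395
sulfite_reduction	Sulfite reduction (dsrAB)	K11180,K11181
co_dehydrogenase_aerobic	Aerobic CO dehydrogenase (coxSML)	K03518,K03519,K03520
nife_hydrogenase	Periplasmic [NiFe] hydrogenase	K06281,K06282
fefe_hydrogenase	NADP-reducing [FeFe] hydrogenase	K00532,K00533,K00534
cytochrome_aa3_oxidase	Cytochrome c oxidase (aa3)	K02274,K02275,K02276
cytochrome_cbb3_oxidase	Microaerobic cytochrome oxidase (cbb3)	K00404,K00405,K00406,K00407
cytochrome_bd_oxidase	Cytochrome bd oxidase	K00425,K00426
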