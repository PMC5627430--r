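#! objective: BIO
#! product: DM_asc
rxn_id	name	equation	lower_bound	upper_bound	subsystem	genes
EX_glc	glucose exchange	glc_e <=> 	-1	1000	exchange	
GLCt	glucose transport	glc_e -> glc_c	0	1000	transport	
GLYC	glycolysis (toy lump)	glc_c -> 3 accoa_c	0	1000	glycolysis	
OX	acetyl-CoA oxidation (toy respiration)	accoa_c + 2 nad_c + 2 h2o_c -> 2 co2_c + 2 nadh_c	0	1000	central carbon metabolism	
ACACT1r	acetyl-CoA C-acetyltransferase	2 accoa_c <=> aacoa_c	-1000	1000	ethylmalonyl-CoA pathway	fadA
HACD1	3-hydroxybutyryl-CoA dehydrogenase	aacoa_c + nadh_c -> hbcoa_c + nad_c	0	1000	ethylmalonyl-CoA pathway	hcd
ECOAH1	3-hydroxybutyryl-CoA dehydratase	hbcoa_c -> b2coa_c + h2o_c	0	1000	ethylmalonyl-CoA pathway	crt
CCCR	crotonyl-CoA carboxylase/reductase	b2coa_c + co2_c + nadh_c -> emcoa_c + nad_c	0	1000	ethylmalonyl-CoA pathway	ccr
SUCS	succinyl-CoA synthesis (toy lump)	2 accoa_c -> succoa_c	0	1000	citric acid cycle	
MMM	methylmalonyl-CoA mutase	succoa_c -> mmcoa_r_c	0	1000	methylmalonyl-CoA metabolism	mcm
MME	methylmalonyl-CoA epimerase	mmcoa_r_c <=> mmcoa_c	-1000	1000	methylmalonyl-CoA metabolism	mce
ASCS	ascomycin synthesis (toy condensation)	emcoa_c + mmcoa_c + accoa_c -> asc_c	0	1000	ascomycin biosynthesis	fkbB
DM_asc	ascomycin sink	asc_c -> 	0.0005	1000	exchange	
BIO	biomass equation (toy)	3 accoa_c + nadh_c -> nad_c	0	1000	biomass	
DRAIN	obligatory overflow drain (toy)	accoa_c -> waste_c	0.05	1000	byproduct secretion	
WASTEt	overflow transport	waste_c -> waste_e	0	1000	transport	
EX_waste	overflow exchange	waste_e -> 	0	1000	exchange	
CO2t	CO2 transport	co2_c -> co2_e	0	1000	transport	
EX_co2	CO2 exchange	co2_e -> 	0	1000	exchange	
H2Ot	water transport	h2o_e <=> h2o_c	-1000	1000	transport	
EX_h2o	water exchange	h2o_e <=> 	-1000	1000	exchange	
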