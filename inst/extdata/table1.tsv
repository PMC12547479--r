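order	family	taxon	taxon_rank	strataseq_detected	morphospecies_id	strataseq_count	sequenced	accession	voucher	benchmark_detected	benchmark_count
Neelipleona	Neelidae	Megalothorax willemi	species	yes	O	9	yes	SRX26802800	BE-COLL-001		
Symphypleona	Arrhopalitidae	Arrhopalites caecus	species							yes	2
Symphypleona	Bourletiellidae	Bourletiella sp.	genus							yes	2
Symphypleona	Dicyrtomidae	Dicyrtomina minuta	species							yes	5
Symphypleona	Katiannidae	Sminthurinus aureus	species	yes	H	36	no	GCA_034698265.1		yes	9
Symphypleona	Katiannidae	Sminthurinus elegans	species	yes	Sb	19	no	GCA_034698325.1		yes	20
Symphypleona	Katiannidae	Sminthurinus alpinus	species							yes	2
Symphypleona	Katiannidae	Sminthurinus signatus	species							yes	7
Symphypleona	Katiannidae	Sminthurinus sp.	genus							yes	18
Symphypleona	Sminthuridae	Sminthurus sp.	genus	yes	M	59	no			yes	2
Symphypleona	Sminthuridae	Sminthurus viridis	species	yes	M		no	GCA_965194885.1			
Symphypleona	Sminthuridae	Sminthurus wahlgreni	species							yes	22
Symphypleona	Sminthuridae	Sphaeridia pumilis	species	yes	V	194	no	GCA_034698345.1		yes	41
Poduromorpha	Brachystomellidae	Brachystomella parvula	species	yes	C	133	no	GCA_019776545.1		yes	8
Poduromorpha	Hypogastruridae	Ceratophysella denticulata	species							yes	9
Poduromorpha	Hypogastruridae	Ceratophysella sp	genus							yes	8
Poduromorpha	Hypogastruridae	Willemia similis	species							yes	1
Poduromorpha	Hypogastruridae	Hypogastrura sp.	genus							yes	3
Poduromorpha	Hypogastruridae	Hypogastrura vernalis	species							yes	7
Poduromorpha	Neanuridae	Friesea truncata	species							yes	9
Poduromorpha	Neanuridae	Micranurida pygmaea	species							yes	1
Poduromorpha	Neanuridae	Pseudachorutes corticicolus	species							yes	14
Poduromorpha	Neanuridae	Pseudachorutes sp	genus							yes	5
Poduromorpha	Tullbergiidae	Mesaphorura critica	species	yes	K	90	yes	SRX26802793	BE-COLL-007	yes	11
Poduromorpha	Tullbergiidae	Mesaphorura hylophila	species	yes	K		yes	SRX26802803			
Poduromorpha	Tullbergiidae	Mesaphorura krausbaueri	species	yes	K		yes	SRX26802804	BE-COLL-008	yes	17
Poduromorpha	Tullbergiidae	Mesaphorura sp.	genus	yes	K		no		BE-COLL-009	yes	1
Poduromorpha	Tullbergiidae	Metaphorura incisa	species	yes	K		yes	SRX26802798	BE-COLL-010		
Poduromorpha	Tullbergiidae	Metaphorura affinis	species	yes	K		yes	SRX26802797	BE-COLL-011	yes	38
Poduromorpha	Tullbergiidae	Stenaphorura quadrispina	species	yes	K		yes	SRX26802796	BE-COLL-012	yes	8
Poduromorpha	Tullbergiidae	Mesaphorura macrochaeta	species							yes	13
Poduromorpha	Tullbergiidae	Mesaphorura sylvatica	species							yes	6
Poduromorpha	Tullbergiidae	Mesaphorura yosii	species							yes	1
Poduromorpha	Onychiuridae	Onychiurus sp.	genus	yes	A	225	yes	SRX26802807	BE-COLL-013		
Poduromorpha	Onychiuridae	Protaphorura bicampata	species	yes	A		no		BE-COLL-014		
Poduromorpha	Onychiuridae	Protaphorura campata	species	yes	A		yes	SRX26802808	BE-COLL-015		
Poduromorpha	Onychiuridae	Protaphorura cancellata	species	yes	A		yes	SRX26802805	BE-COLL-016		
Poduromorpha	Onychiuridae	Protaphorura sp.	genus	yes	A		no			yes	5
Poduromorpha	Onychiuridae	Protaphorura subuliginata	species	yes	A		yes	SRX26802792	BE-COLL-018		
Poduromorpha	Onychiuridae	Protaphorura armata	species	yes	A		no	GCA_034700305.1		yes	64
Poduromorpha	Onychiuridae	Onychiurus cebennarius	species							yes	8
Poduromorpha	Onychiuridae	Onychiurus edinensis	species							yes	2
Entomobryomorpha	Entomobryidae	Lepidocyrtus cyaneus	species	yes	G	62	no	GCA_034696785.1		yes	58
Entomobryomorpha	Entomobryidae	Lepidocyrtus lanuginosus	species	yes	D	71	yes	SRX26802809	BE-COLL-021	yes	21
Entomobryomorpha	Entomobryidae	Lepidocyrtus pallidus	species	yes	D		no		BE-COLL-022		
Entomobryomorpha	Entomobryidae	Lepidocyrtus sp. - possibly lignorum	genus	yes	D		no	GCA_034696835.1			
Entomobryomorpha	Entomobryidae	Lepidocyrtus sp.	genus	yes	D		no		BE-COLL-023	yes	34
Entomobryomorpha	Entomobryidae	Lepidocyrtus lignorum	species							yes	12
Entomobryomorpha	Entomobryidae	Lepidocyrtus curvicollis	species							yes	1
Entomobryomorpha	Entomobryidae	Entomobrya multifasciata	species							yes	10
Entomobryomorpha	Entomobryidae	Entomobrya nivalis	species							yes	1
Entomobryomorpha	Entomobryidae	Entomobrya sp.	genus							yes	29
Entomobryomorpha	Entomobryidae	Pseudosinella alba	species	yes	F	37	no	GCA_034700485.1		yes	12
Entomobryomorpha	Entomobryidae	Pseudosinella immaculata	species							yes	2
Entomobryomorpha	Isotomidae	Cyphoderus albinus	species	yes	U	19	no	GCA_965194875.1			
Entomobryomorpha	Isotomidae	Desoria duodecemoculata	species							yes	7
Entomobryomorpha	Isotomidae	Folsomia fimetaria	species	yes	I	46	no	GCA_034695645.1		yes	2
Entomobryomorpha	Isotomidae	Folsomia manolachei	species	yes	L	149	yes	SRX26802802	BE-COLL-027	yes	51
Entomobryomorpha	Isotomidae	Folsomia quadrioculata	species	yes	L		yes	SRX26802810	BE-COLL-028	yes	48
Entomobryomorpha	Isotomidae	Folsomia lawrencei	species							yes	6
Entomobryomorpha	Isotomidae	Folsomia sp.	genus							yes	1
Entomobryomorpha	Isotomidae	Folsomides parvulus	species							yes	7
Entomobryomorpha	Isotomidae	Isotoma caerulea	species	yes	E	37	no	GCA_034696405.1			
Entomobryomorpha	Isotomidae	Isotoma sp. (prob. anglicana or cearulea)	genus	yes	E		no	GCA_034694685.1			
Entomobryomorpha	Isotomidae	Isotoma viridis	species	yes	E		no	GCA_034696425.1		yes	6
Entomobryomorpha	Isotomidae	Isotomurus sp.	genus	yes	E		no				
Entomobryomorpha	Isotomidae	Isotoma anglicana	species							yes	55
Entomobryomorpha	Isotomidae	Isotomurus fucicola	species							yes	41
Entomobryomorpha	Isotomidae	Isotomiella minor	species							yes	29
Entomobryomorpha	Isotomidae	Isotomodes productus	species	yes	Q	21	yes	SRX26802799	BE-COLL-033	yes	42
Entomobryomorpha	Isotomidae	Parisotoma ekmani	species	yes	Ia	40	no		BE-COLL-034		
Entomobryomorpha	Isotomidae	Cryptopygus bipunctatus	species	yes	Ia		yes	SRX26802801	BE-COLL-035	yes	4
Entomobryomorpha	Isotomidae	Cryptopygus ponticus	species							yes	1
Entomobryomorpha	Isotomidae	Parisotoma notabilis	species	yes	B	989	yes	SRX26802806	BE-COLL-036	yes	366
Entomobryomorpha	Isotomidae	Proisotoma minima	species							yes	1
Entomobryomorpha	Isotomidae	Parisotoma sp.	genus							yes	3
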