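#KB toy_liver_drug
// Miniature drug / liver-disorder ontology in the toy TSV dialect.
// CONCEPTS: code <TAB> source <TAB> preferred_name <TAB> synonyms(;) <TAB> semantic_type
#CONCEPTS
D0001	TOYRX	drug	medication;medicine	Drug
D0002	TOYRX	aspirin	acetylsalicylic acid	Drug
D0003	TOYRX	atenolol		Drug
D0004	TOYRX	trazodone		Drug
D0005	TOYRX	wellbutrin	bupropion	Drug
D0006	TOYRX	diovan	valsartan	Drug
D0007	TOYRX	tazorac	tazarotene	Drug
D0008	TOYRX	retin a	tretinoin;retin a micro	Drug
C0001	TOYDX	condition	disorder	Condition
C0002	TOYDX	headache		Condition
C0003	TOYDX	liver disorder		Condition
C0004	TOYDX	cirrhosis		Condition
C0005	TOYDX	cirrhotic ascites		Condition
C0006	TOYDX	grogginess	groggy	Condition
C0007	TOYDX	low libido		Condition
C0008	TOYDX	panic disorder		Condition
C0009	TOYDX	smoking		Condition
#RELATIONS
D0002	IS_A	D0001
D0003	IS_A	D0001
D0004	IS_A	D0001
D0005	IS_A	D0001
D0006	IS_A	D0001
D0007	IS_A	D0001
D0008	IS_A	D0001
C0002	IS_A	C0001
C0003	IS_A	C0001
C0004	IS_A	C0003
C0005	IS_A	C0004
C0006	IS_A	C0001
C0007	IS_A	C0001
C0008	IS_A	C0001
D0002	may_treat	C0002
D0006	may_treat	C0003
D0004	associated_with	C0006
D0005	may_treat	C0008
D0005	associated_with	C0009
D0003	associated_with	C0007
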