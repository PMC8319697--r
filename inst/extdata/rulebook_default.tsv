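tc	Treatment	1	therapy	FALSE
tc	Treatment	1	treating	FALSE
tc	Treatment	1	cure	FALSE
tc	Treatment	1	remedy	FALSE
tc	Treatment	1	inhibit	FALSE
tc	Cause	2	induce	FALSE
tc	Cause	2	cause	FALSE
tc	Cause	2	side effect	FALSE
tc	Cause	2	influence	FALSE
tc	Cause	2	dynamic	FALSE
ddi	Advise	1	avoid	FALSE
ddi	Advise	1	should not be	FALSE
ddi	Interaction	2	interaction	FALSE
ddi	Interaction	2	and	TRUE
ddi	Interaction	2	between	TRUE
ddi	Effect	3	enhance	FALSE
ddi	Effect	3	against	FALSE
ddi	Effect	3	demonstrated	FALSE
ddi	Mechanism	4	metabolize	FALSE
ddi	Mechanism	4	decrease	FALSE
ddi	Mechanism	4	increase	FALSE
ddi	Negative	5	no	TRUE
ddi	EntityOrigin	6	include	FALSE
ddi	EntityOrigin	6	contain	FALSE
assoc	PositiveAssociation	1	effect	FALSE
assoc	PositiveAssociation	1	induce	FALSE
assoc	PositiveAssociation	1	target	FALSE
assoc	NegativeAssociation	2	indifference	FALSE
assoc	NegativeAssociation	2	no	TRUE
tc	Other	7		
ddi	Other	7		
assoc	Other	7		
#mode: stem
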