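# Worked-example hypernym taxonomy: the complete noun chain for "cat"
# (depth 10 below the root "entity", "animal" at depth 3), the generic
# noun "thing" (depth 1), chains for "water"/"door"/"sink", and two small
# verb trees ("close" depth 1, "come out" depth 3).
# Dialect: S<TAB>id<TAB>pos<TAB>lemma1|lemma2...<TAB>gloss ; E<TAB>hyponym<TAB>hypernym
S	n001	noun	entity	that which is perceived to have its own distinct existence
S	n002	noun	thing	a separate and self-contained entity
S	n003	noun	object	a tangible and visible entity
S	n004	noun	living thing|animate thing	a living organism
S	n005	noun	animal|animate being|beast	a living organism characterized by voluntary movement
S	n006	noun	chordate	animals having a notochord or spinal column
S	n007	noun	vertebrate|craniate	animals having a bony or cartilaginous skeleton
S	n008	noun	mammal	warm-blooded vertebrate having the skin covered with hair
S	n009	noun	placental|placental mammal	mammals having a placenta
S	n010	noun	carnivore	a terrestrial or aquatic flesh-eating mammal
S	n011	noun	feline|felid	any of various lithe-bodied roundheaded fissiped mammals
S	n012	noun	cat|true cat	feline mammal usually having thick soft fur
S	n013	noun	substance	that which has mass and occupies space
S	n014	noun	compound|chemical compound	a substance formed by chemical union of elements
S	n015	noun	binary compound	a compound of two elements
S	n016	noun	oxide	any compound of oxygen with another element
S	n017	noun	water|H2O	a binary compound that occurs at room temperature as a liquid
S	n018	noun	whole|unit	an assemblage of parts regarded as a single entity
S	n019	noun	artifact|artefact	a man-made object
S	n020	noun	structure|construction	a thing constructed of parts
S	n021	noun	obstruction|obstructor	any structure that makes progress difficult
S	n022	noun	barrier	a structure or object that impedes free movement
S	n023	noun	door	a swinging or sliding barrier that closes an entrance
S	n024	noun	instrumentality|instrumentation	an artifact that is instrumental in accomplishing some end
S	n025	noun	equipment	an instrumentality needed for an undertaking
S	n026	noun	fixture	an object firmly fixed in place
S	n027	noun	plumbing fixture	a fixture for the distribution and use of water
S	n028	noun	sink	plumbing fixture consisting of a water basin and drainpipe
S	v001	verb	change	undergo a change
S	v002	verb	close|shut	move so that an opening or passage is obstructed
S	v003	verb	happen|occur	come to pass
S	v004	verb	appear	come into sight or view
S	v005	verb	emerge	come out into view
S	v006	verb	come out|come forth	come out of
E	n002	n001
E	n003	n001
E	n004	n003
E	n005	n004
E	n006	n005
E	n007	n006
E	n008	n007
E	n009	n008
E	n010	n009
E	n011	n010
E	n012	n011
E	n013	n003
E	n014	n013
E	n015	n014
E	n016	n015
E	n017	n016
E	n018	n003
E	n019	n018
E	n020	n019
E	n021	n020
E	n022	n021
E	n023	n022
E	n024	n019
E	n025	n024
E	n026	n025
E	n027	n026
E	n028	n027
E	v002	v001
E	v004	v003
E	v005	v004
E	v006	v005
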