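surface	lemma	pos
the	the	DT
a	a	DT
an	an	DT
this	this	DT
these	these	DT
that	that	DT
its	its	PRP$
their	their	PRP$
it	it	PRP
and	and	CC
or	or	CC
of	of	IN
in	in	IN
from	from	IN
with	with	IN
for	for	IN
through	through	IN
as	as	IN
was	be	VBD
were	be	VBD
is	be	VBZ
are	be	VBP
be	be	VB
been	be	VBN
can	can	MD
bacterium	bacterium	NN
bacteria	bacterium	NNS
contact	contact	NN
animal	animal	NN
animals	animal	NNS
product	product	NN
products	product	NNS
air	air	NN
genus	genus	NN
strain	strain	NN
river	river	NN
sediment	sediment	NN
group	group	NN
organism	organism	NN
organisms	organism	NNS
tract	tract	NN
disease	disease	NN
diseases	disease	NNS
inhabitant	inhabitant	NN
human	human	NN
humans	human	NNS
feces	feces	NNS
infant	infant	NN
colonization	colonization	NN
mucosa	mucosa	NN
gut	gut	NN
environment	environment	NN
plant	plant	NN
plants	plant	NNS
sample	sample	NN
samples	sample	NNS
mouse	mouse	NN
cheese	cheese	NN
fluid	fluid	NN
analysis	analysis	NN
mummy	mummy	NN
tissue	tissue	NN
tissues	tissue	NNS
intestine	intestine	NN
rhizosphere	rhizosphere	NN
cavity	cavity	NN
skin	skin	NN
lesion	lesion	NN
patient	patient	NN
stem	stem	NN
nodule	nodule	NN
isolate	isolate	NN
water	water	NN
highly	highly	RB
initially	initially	RB
infectious	infectious	JJ
infected	infected	JJ
environmental	environmental	JJ
respiratory	respiratory	JJ
severe	severe	JJ
normal	normal	JJ
gastrointestinal	gastrointestinal	JJ
pharyngeal	pharyngeal	JJ
iron-rich	iron-rich	JJ
wet	wet	JJ
bodily	bodily	JJ
small	small	JJ
oral	oral	JJ
capable	capable	JJ
spread	spread	VB
invading	invade	VBG
causing	cause	VBG
isolated	isolate	VBN
observed	observe	VBN
grows	grow	VBZ
infects	infect	VBZ
taken	take	VBN
collected	collect	VBN
sampled	sample	VBN
examined	examine	VBN
lives	live	VBZ
found	find	VBN
obtained	obtain	VBN
reported	report	VBN
Brucella	Brucella	NNP
canis	canis	NNP
Borrelia	Borrelia	NNP
burgdorferi	burgdorferi	NNP
Ixodes	Ixodes	NNP
scapularis	scapularis	NNP
Bordetella	Bordetella	NNP
petrii	petrii	NNP
DSM12804	DSM12804	NNP
Bifidobacterium	Bifidobacterium	NNP
longum	longum	NNP
NCC2705	NCC2705	NNP
Pseudomonas	Pseudomonas	NNP
fluorescens	fluorescens	NNP
Streptococcus	Streptococcus	NNP
mutans	mutans	NNP
Bradyrhizobium	Bradyrhizobium	NNP
Aeschynomene	Aeschynomene	NNP
Lyme	Lyme	NNP
Europe	Europe	NNP
Germany	Germany	NNP
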