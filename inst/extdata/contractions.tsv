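# static contraction map: token<TAB>expansion (applied token-wise after
# normalization; includes common apostrophe-less variants)
ain't	is not
aren't	are not
can't	can not
cannot	can not
could've	could have
couldn't	could not
didn't	did not
doesn't	does not
don't	do not
hadn't	had not
hasn't	has not
haven't	have not
he'd	he would
he'll	he will
he's	he is
here's	here is
how'd	how did
how'll	how will
how's	how is
i'd	i would
i'll	i will
i'm	i am
i've	i have
isn't	is not
it'd	it would
it'll	it will
it's	it is
let's	let us
mightn't	might not
might've	might have
mustn't	must not
must've	must have
needn't	need not
she'd	she would
she'll	she will
she's	she is
should've	should have
shouldn't	should not
that'd	that would
that'll	that will
that's	that is
there'd	there would
there'll	there will
there's	there is
they'd	they would
they'll	they will
they're	they are
they've	they have
wasn't	was not
we'd	we would
we'll	we will
we're	we are
we've	we have
weren't	were not
what'd	what did
what'll	what will
what're	what are
what's	what is
what've	what have
when's	when is
where'd	where did
where's	where is
who'd	who would
who'll	who will
who're	who are
who's	who is
who've	who have
why'd	why did
why's	why is
won't	will not
would've	would have
wouldn't	would not
y'all	you all
you'd	you would
you'll	you will
you're	you are
you've	you have
aint	is not
arent	are not
cant	can not
couldnt	could not
didnt	did not
doesnt	does not
dont	do not
hadnt	had not
hasnt	has not
havent	have not
im	i am
isnt	is not
ive	i have
lets	let us
shouldnt	should not
thats	that is
theyre	they are
wasnt	was not
werent	were not
weve	we have
wont	will not
wouldnt	would not
youre	you are
youve	you have
gonna	going to
gotta	got to
wanna	want to
lemme	let me
dunno	do not know
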