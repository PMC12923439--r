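# strict tier (adds to default): degree adverbs, deictics, wh-adverbs,
# light/delexicalized verbs, discourse markers and vague nouns
very
really
quite
rather
just
too
almost
always
never
often
sometimes
usually
again
still
even
only
now
then
there
here
when
where
why
how
more
less
least
enough
indeed
perhaps
maybe
actually
basically
literally
anyway
anyhow
alright
also
get
gets
got
gotten
getting
go
goes
going
went
gone
come
comes
coming
came
say
says
said
saying
know
knows
knew
known
knowing
think
thinks
thought
thinking
mean
means
meant
meaning
want
wants
wanted
wanting
see
sees
saw
seen
make
makes
made
making
take
takes
took
taken
put
lot
lots
bit
way
kind
sort
stuff
thing
things
right
sure
you know
i mean
sort of
kind of
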