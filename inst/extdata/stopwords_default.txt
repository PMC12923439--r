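# default tier (adds to minimal): determiners, adpositions, pronouns,
# auxiliaries/copula, modal auxiliaries, conjunctions, Arabic numerals 0-12
# (digits and number words), greetings and idioms (multi-word entries are
# matched as phrases on the expanded token stream)
this
that
these
those
each
every
either
neither
some
any
all
both
few
many
much
most
other
another
such
of
in
on
at
by
for
with
about
against
between
into
through
during
before
after
above
below
to
from
up
down
out
off
over
under
near
upon
onto
within
without
across
along
around
behind
beneath
beside
besides
beyond
except
inside
outside
toward
towards
underneath
until
via
i
me
my
mine
myself
we
us
our
ours
ourselves
you
your
yours
yourself
yourselves
he
him
his
himself
she
her
hers
herself
it
its
itself
they
them
their
theirs
themselves
who
whom
whose
which
what
anybody
anyone
anything
everybody
everyone
everything
nobody
nothing
somebody
someone
something
am
is
are
was
were
be
been
being
do
does
did
done
have
has
had
having
can
could
may
might
must
shall
should
will
would
ought
need
and
or
but
if
because
as
while
than
nor
so
yet
though
although
whether
unless
since
not
0
1
2
3
4
5
6
7
8
9
10
11
12
zero
one
two
three
four
five
six
seven
eight
nine
ten
eleven
twelve
like
hello
hi
goodbye
bye
thanks
how is it going
how are you
how are you doing
good morning
good afternoon
good evening
good night
thank you
nice to meet you
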