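a
an
the
this
that
these
those
each
every
any
some
no
both
all
another
is
are
was
were
be
been
being
am
do
does
did
have
has
had
can
could
will
would
shall
should
may
might
must
of
in
on
for
with
to
from
by
at
as
into
after
before
between
during
against
about
over
under
through
within
among
upon
via
it
its
they
them
their
he
she
his
her
we
you
i
our
your
us
me
itself
themselves
and
or
but
nor
not
what
which
who
whom
whose
where
when
why
how
there
here
than
then
so
such
also
very
more
most
less
least
only
own
same
too
s
t
just
now
again
further
once
out
up
down
off
above
below
because
while
until
if
whether
however
therefore
thus
moreover
furthermore
respectively
e.g
i.e
etc
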