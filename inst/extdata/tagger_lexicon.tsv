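word	tag
a	DET
an	DET
the	DET
this	DET
that	DET
these	DET
those	DET
each	DET
every	DET
some	DET
any	DET
no	DET
of	PREP
in	PREP
on	PREP
at	PREP
by	PREP
for	PREP
with	PREP
from	PREP
to	PREP
into	PREP
onto	PREP
within	PREP
without	PREP
between	PREP
among	PREP
during	PREP
via	PREP
under	PREP
over	PREP
through	PREP
after	PREP
before	PREP
across	PREP
against	PREP
toward	PREP
towards	PREP
upon	PREP
per	PREP
as	PREP
is	VERB
are	VERB
was	VERB
were	VERB
be	VERB
been	VERB
being	VERB
am	VERB
has	VERB
have	VERB
had	VERB
do	VERB
does	VERB
did	VERB
can	VERB
could	VERB
may	VERB
might	VERB
will	VERB
would	VERB
should	VERB
must	VERB
suggest	VERB
suggests	VERB
show	VERB
shows	VERB
showed	VERB
shown	VERB
indicate	VERB
indicates	VERB
remain	VERB
remains	VERB
contain	VERB
contains	VERB
divide	VERB
divides	VERB
cause	VERB
causes	VERB
encode	VERB
encodes	VERB
and	OTHER
or	OTHER
but	OTHER
nor	OTHER
so	OTHER
yet	OTHER
while	OTHER
whereas	OTHER
although	OTHER
because	OTHER
if	OTHER
when	OTHER
where	OTHER
which	OTHER
who	OTHER
whom	OTHER
whose	OTHER
however	OTHER
therefore	OTHER
moreover	OTHER
furthermore	OTHER
also	OTHER
not	OTHER
then	OTHER
thus	OTHER
here	OTHER
there	OTHER
it	OTHER
its	OTHER
they	OTHER
them	OTHER
their	OTHER
we	OTHER
our	OTHER
us	OTHER
he	OTHER
she	OTHER
his	OTHER
her	OTHER
i	OTHER
you	OTHER
your	OTHER
both	OTHER
only	OTHER
very	OTHER
more	OTHER
most	OTHER
other	ADJ
new	ADJ
novel	ADJ
major	ADJ
minor	ADJ
common	ADJ
rare	ADJ
potent	ADJ
important	ADJ
essential	ADJ
effective	ADJ
complex	ADJ
human	ADJ
murine	ADJ
putative	ADJ
specific	ADJ
several	ADJ
many	ADJ
few	ADJ
single	ADJ
high	ADJ
low	ADJ
large	ADJ
small	ADJ
describe	VERB
describes	VERB
propose	VERB
proposes	VERB
demonstrate	VERB
demonstrates	VERB
reveal	VERB
reveals	VERB
perform	VERB
performs	VERB
investigate	VERB
investigates	VERB
identify	VERB
identifies	VERB
examine	VERB
examines	VERB
observe	VERB
observes	VERB
consider	VERB
considers	VERB
considered	VERB
require	VERB
requires	VERB
involve	VERB
involves	VERB
obtain	VERB
obtains	VERB
produce	VERB
produces	VERB
induce	VERB
induces	VERB
inhibit	VERB
inhibits	VERB
activate	VERB
activates	VERB
regulate	VERB
regulates	VERB
mediate	VERB
mediates	VERB
report	VERB
reports	VERB
controls	VERB
control	VERB
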