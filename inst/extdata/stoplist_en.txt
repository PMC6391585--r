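the
and
for
are
but
not
you
all
any
can
had
her
was
one
our
out
day
get
has
him
his
how
man
new
now
old
see
two
way
who
boy
did
its
let
put
say
she
too
use
about
above
after
again
against
also
among
around
because
been
before
being
below
between
both
came
come
could
does
doing
done
down
during
each
early
even
ever
every
fact
felt
few
find
first
from
gave
give
given
goes
going
good
great
group
hand
have
having
head
hear
heard
held
help
here
high
himself
herself
hold
home
house
into
itself
just
keep
kept
kind
knew
know
known
large
last
late
later
least
leave
left
less
life
like
line
little
long
look
made
make
making
many
matter
mean
means
might
more
most
much
must
name
near
need
never
next
none
nothing
number
often
once
only
open
order
other
others
over
own
part
people
place
point
public
quite
rather
real
right
round
said
same
saw
says
second
seem
seemed
seems
seen
several
shall
short
should
show
showed
shown
shows
side
since
small
some
something
soon
still
such
sure
take
taken
tell
than
that
them
then
there
these
they
thing
things
think
third
this
those
though
thought
three
through
thus
time
times
together
told
took
toward
turn
under
until
upon
used
using
very
want
water
well
went
were
what
when
where
which
while
white
whole
whom
whose
will
with
within
without
word
words
work
world
would
year
years
young
your
able
across
act
add
age
ago
air
almost
alone
along
already
although
always
amount
another
answer
anyone
anything
appear
area
ask
asked
away
back
bad
based
become
becomes
began
begin
behind
best
better
beyond
big
bit
black
body
book
bring
brought
built
business
call
called
car
care
carried
carry
case
cases
cause
certain
change
changes
city
class
clear
clearly
close
common
company
complete
concern
consider
control
cost
country
course
court
cut
data
deal
death
decided
deep
describe
despite
detail
develop
difference
different
difficult
direct
door
doubt
due
each
effect
effort
eight
either
else
end
enough
entire
especially
etc
evidence
example
except
expect
experience
eye
eyes
face
fall
family
far
fast
father
feel
feet
fell
field
figure
fill
final
finally
fine
fire
five
follow
following
food
foot
force
form
found
four
free
front
full
further
game
general
get
gets
girl
got
govern
ground
grow
half
hard
having
hear
heart
heavy
held
herself
himself
history
hope
hour
hours
however
human
hundred
idea
important
include
included
includes
including
increase
indeed
information
inside
instead
interest
issue
job
key
kind
knowledge
land
language
law
lay
lead
learn
led
level
light
likely
list
live
lived
local
longer
lost
lot
love
low
main
major
makes
market
may
maybe
meant
meet
member
members
men
method
middle
mind
minutes
moment
money
month
months
morning
mother
move
moved
music
myself
nation
national
natural
nature
nearly
necessary
needed
needs
neither
night
nine
nor
note
nothing
object
observe
obtain
obtained
occur
off
office
one
onto
order
outside
page
paper
particular
party
passed
past
pay
per
perhaps
period
person
picture
piece
plan
play
poor
position
possible
power
present
president
pressure
probably
problem
problems
process
produce
program
provide
provided
purpose
question
questions
quickly
raise
ran
range
rate
read
ready
reason
received
recent
recently
record
red
remain
remember
report
require
required
research
respect
rest
result
results
return
returned
road
role
room
rule
run
sat
school
sea
season
seat
section
sense
sent
series
service
set
seven
shape
share
sharp
ship
shot
simple
simply
single
sit
situation
six
size
social
society
someone
sometimes
son
sort
sound
space
speak
special
specific
spent
spoke
stage
stand
start
started
state
states
stay
step
stood
stop
story
street
strong
study
subject
success
suddenly
suggest
support
system
table
talk
tax
team
ten
term
terms
test
theory
therefore
thing
thinking
thirty
thousand
thus
today
top
total
town
trade
tried
true
try
trying
turned
type
understand
unit
value
various
view
voice
wall
wanted
war
watch
week
weeks
whether
wide
wife
win
window
wish
woman
women
write
written
wrong
yes
yet
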