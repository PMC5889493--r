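a
about
above
across
act
add
afraid
after
afternoon
again
against
age
ago
agree
air
all
almost
alone
along
already
also
always
am
among
an
and
angry
animal
another
answer
any
anyone
anything
appear
apple
are
arm
around
arrive
art
as
ask
at
ate
aunt
away
baby
back
bad
bag
ball
band
bank
bar
barn
base
basket
bath
be
bear
beat
beautiful
became
because
become
bed
been
before
began
begin
behind
believe
bell
belong
below
beside
best
better
between
big
bill
bird
birthday
bit
bite
black
blow
blue
board
boat
body
bone
book
born
both
bottle
bottom
bought
box
boy
branch
bread
break
breakfast
bridge
bright
bring
broke
brother
brought
brown
build
burn
bus
busy
but
butter
buy
by
cake
call
came
camp
can
cap
car
card
care
careful
carry
case
cat
catch
caught
cause
center
chair
chance
change
chest
chicken
child
children
church
circle
city
class
clean
clear
climb
clock
close
cloth
clothes
cloud
coat
cold
color
come
company
cook
cool
corn
corner
cost
could
count
country
course
cover
cow
cried
cross
crowd
cry
cup
cut
dad
dance
dark
day
dead
dear
decide
deep
desk
did
die
different
dig
dinner
dish
do
doctor
does
dog
done
door
down
draw
dream
dress
drink
drive
drop
dry
duck
during
dust
each
ear
early
earth
east
easy
eat
edge
egg
eight
either
else
empty
end
enjoy
enough
enter
even
evening
ever
every
everyone
everything
eye
face
fact
fall
family
far
farm
farmer
fast
fat
father
fear
feed
feel
feet
fell
felt
few
field
fight
fill
find
fine
finger
finish
fire
first
fish
fit
five
fix
floor
flower
fly
follow
food
foot
for
forest
forget
form
found
four
fresh
friend
from
front
fruit
full
fun
funny
game
garden
gate
gave
get
gift
girl
give
glad
glass
go
goes
going
gold
gone
good
got
grass
gray
great
green
grew
ground
group
grow
guess
had
hair
half
hand
happen
happy
hard
has
hat
have
he
head
hear
heard
heart
heavy
held
hello
help
her
here
herself
hid
hide
high
hill
him
himself
his
hit
hold
hole
home
hope
horse
hot
hour
house
how
hundred
hungry
hunt
hurry
hurt
i
ice
idea
if
important
in
inside
into
is
it
its
job
join
jump
just
keep
kept
kick
kill
kind
king
kitchen
knee
knew
know
lady
lake
land
large
last
late
laugh
lay
lead
learn
leave
left
leg
less
let
letter
life
lift
light
like
line
lion
list
listen
little
live
long
look
lost
lot
loud
love
low
lunch
made
mail
make
man
many
map
mark
market
may
me
mean
meat
meet
men
met
middle
might
mile
milk
mind
mine
minute
miss
moment
money
month
moon
more
morning
most
mother
mountain
mouse
mouth
move
much
music
must
my
name
near
neck
need
never
new
next
nice
night
nine
no
noise
none
north
nose
not
note
nothing
now
number
ocean
of
off
office
often
old
on
once
one
only
open
or
orange
order
other
our
out
outside
over
own
page
paint
pair
paper
parent
park
part
party
pass
past
pay
pen
pencil
people
perhaps
person
pick
picture
piece
pig
place
plan
plant
play
please
pocket
point
poor
pretty
pull
push
put
queen
question
quick
quiet
rabbit
race
rain
ran
reach
read
ready
real
red
remember
rest
ride
right
ring
river
road
rock
roll
roof
room
round
row
run
sad
safe
said
sail
salt
same
sand
sat
save
saw
say
school
sea
seat
second
see
seed
seem
seen
sell
send
sent
set
seven
shall
shape
she
sheep
shine
ship
shoe
shop
short
should
shout
show
sick
side
sign
silver
simple
since
sing
sister
sit
six
size
sky
sleep
slow
small
smell
smile
snow
so
soft
sold
some
someone
something
song
soon
sound
south
space
speak
spell
spend
spot
spring
stand
star
start
stay
step
stick
still
stone
stood
stop
store
story
street
strong
such
sudden
summer
sun
supper
sure
surprise
sweet
swim
table
tail
take
talk
tall
taste
teach
teacher
team
tell
ten
than
thank
that
the
their
them
then
there
these
they
thick
thin
thing
think
third
this
those
though
thought
three
through
throw
tie
time
tiny
tired
to
today
together
told
tomorrow
too
took
top
touch
toward
town
toy
train
tree
tried
trip
truck
true
try
turn
twelve
twenty
two
uncle
under
until
up
upon
us
use
very
visit
voice
wait
walk
wall
want
warm
was
wash
watch
water
wave
way
we
wear
weather
week
well
went
were
west
wet
what
wheel
when
where
which
while
white
who
whole
why
wide
wild
will
win
wind
window
wing
winter
wish
with
without
woman
women
wood
word
wore
work
world
would
write
wrong
yard
year
yellow
yes
yesterday
yet
you
young
your
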