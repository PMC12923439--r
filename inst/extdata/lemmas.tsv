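# static lemma dictionary: inflected form<TAB>dictionary form
answered	answer
answering	answer
answers	answer
apples	apple
arms	arm
ate	eat
babies	baby
bags	bag
balls	ball
beaches	beach
beds	bed
believed	believe
believes	believe
believing	believe
best	good
better	good
bigger	big
biggest	big
birds	bird
bones	bone
books	book
boxes	box
breaking	break
breaks	break
brighter	bright
brightest	bright
broke	break
broken	break
brothers	brother
building	build
builds	build
built	build
cars	car
cats	cat
chairs	chair
changed	change
changes	change
changing	change
children	child
cities	city
cleaned	clean
cleaning	clean
cleans	clean
clocks	clock
closed	close
closes	close
closing	close
clouds	cloud
coats	coat
colder	cold
coldest	cold
colors	color
computers	computer
cooked	cook
cooking	cook
cooks	cook
cried	cry
cries	cry
crying	cry
cups	cup
danced	dance
dances	dance
dancing	dance
darker	dark
darkest	dark
died	die
dies	die
dinners	dinner
doctors	doctor
dogs	dog
doors	door
drank	drink
dreaming	dream
dreams	dream
dreamt	dream
drinking	drink
drinks	drink
driven	drive
drives	drive
driving	drive
drove	drive
drunk	drink
dying	die
eaten	eat
eating	eat
eats	eat
explained	explain
explaining	explain
explains	explain
eyes	eye
faces	face
farms	farm
faster	fast
fastest	fast
fathers	father
feeling	feel
feels	feel
feet	foot
felt	feel
fields	field
finding	find
finds	find
fishes	fish
flew	fly
flies	fly
floors	floor
flowers	flower
flown	fly
flying	fly
forests	forest
forgets	forget
forgetting	forget
forgot	forget
forgotten	forget
found	find
friends	friend
fruits	fruit
games	game
gardens	garden
gave	give
gifts	gift
given	give
gives	give
giving	give
grew	grow
growing	grow
grown	grow
grows	grow
hands	hand
happier	happy
happiest	happy
harder	hard
hardest	hard
hated	hate
hates	hate
hating	hate
hats	hat
healed	heal
healing	heal
heals	heal
heard	hear
hearing	hear
hears	hear
hearts	heart
held	hold
helped	help
helping	help
helps	help
holding	hold
holds	hold
homes	home
hoped	hope
hopes	hope
hoping	hope
horses	horse
houses	house
hurted	hurt
hurting	hurt
hurts	hurt
ideas	idea
jobs	job
jumped	jump
jumping	jump
jumps	jump
keeping	keep
keeps	keep
kept	keep
keys	key
kitchens	kitchen
knives	knife
laughed	laugh
laughing	laugh
laughs	laugh
learned	learn
learning	learn
learns	learn
leaves	leave
leaving	leave
left	leave
legs	leg
letters	letter
listened	listen
listening	listen
listens	listen
lived	live
lives	life
living	live
locks	lock
longer	long
longest	long
loses	lose
losing	lose
lost	lose
louder	loud
loudest	loud
loved	love
loves	love
loving	love
meeting	meet
meets	meet
men	man
met	meet
mice	mouse
moneys	money
mornings	morning
mothers	mother
mountains	mountain
muscles	muscle
nights	night
noises	noise
oceans	ocean
older	old
oldest	old
opened	open
opening	open
opens	open
painted	paint
painting	paint
paints	paint
papers	paper
pens	pen
phones	phone
pictures	picture
plates	plate
played	play
playing	play
plays	play
poorer	poor
poorest	poor
problems	problem
questions	question
quieter	quiet
quietest	quiet
ran	run
reading	read
reads	read
reasons	reason
remembered	remember
remembering	remember
remembers	remember
returned	return
returning	return
returns	return
richer	rich
richest	rich
rivers	river
roads	road
roofs	roof
rooms	room
running	run
runs	run
sadder	sad
saddest	sad
sang	sing
sat	sit
schools	school
shadows	shadow
shoes	shoe
shorter	short
shortest	short
shouted	shout
shouting	shout
shouts	shout
singing	sing
sings	sing
sisters	sister
sits	sit
sitting	sit
sleeping	sleep
sleeps	sleep
slept	sleep
slower	slow
slowest	slow
smaller	small
smallest	small
smelled	smell
smelling	smell
smells	smell
smiled	smile
smiles	smile
smiling	smile
softer	soft
softest	soft
songs	song
sounds	sound
speaking	speak
speaks	speak
spoke	speak
spoken	speak
spoons	spoon
standing	stand
stands	stand
stars	star
started	start
starting	start
starts	start
stayed	stay
staying	stay
stays	stay
stones	stone
stood	stand
stoped	stop
stoping	stop
stops	stop
stories	story
storms	storm
streets	street
stronger	strong
strongest	strong
summers	summer
sung	sing
swam	swim
sweeter	sweet
sweetest	sweet
swimming	swim
swims	swim
swum	swim
tables	table
talked	talk
talking	talk
talks	talk
taller	tall
tallest	tall
tasted	taste
tastes	taste
tasting	taste
taught	teach
teachers	teacher
teaches	teach
teaching	teach
teeth	tooth
touched	touch
touches	touch
touching	touch
trains	train
traveled	travel
traveling	travel
travels	travel
trees	tree
understanding	understand
understands	understand
understood	understand
villages	village
visited	visit
visiting	visit
visits	visit
voices	voice
walked	walk
walking	walk
walks	walk
walls	wall
warmer	warm
warmest	warm
washed	wash
washes	wash
washing	wash
watched	watch
watches	watch
watching	watch
weaker	weak
weakest	weak
whispered	whisper
whispering	whisper
whispers	whisper
windows	window
winters	winter
wolves	wolf
women	woman
words	word
worse	bad
worst	bad
writes	write
writing	write
written	write
wrote	write
younger	young
youngest	young
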