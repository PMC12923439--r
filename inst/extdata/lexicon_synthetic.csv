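headword,valence,concreteness,freq_lg10,letters,morphemes
afraid,2.71,1.85,3.49,6,1
anger,2,2.1,4.14,5,2
angry,1.58,1.8,4.17,5,1
answer,5.41,1.93,3.63,6,2
apple,4.93,4.59,4.01,5,1
arm,4.72,4.73,4.77,3,1
awful,1.81,1.5,3.9,5,1
baby,5.46,4.74,4.53,4,1
bad,2.48,2.23,4.72,3,1
bag,5.55,4.09,5.02,3,1
ball,5.82,4.52,4.44,4,1
beach,5.5,4.99,4.11,5,1
beautiful,7.93,1.46,1.94,9,2
bed,5.17,4.74,5.44,3,1
believe,4.76,2.92,2.88,7,1
big,4.99,3.17,4.53,3,1
bird,5.15,5,4.78,4,1
bitter,2.49,1.19,3.56,6,2
blood,7.12,4,4.17,5,1
bone,4.43,4.64,4.21,4,1
book,5.71,4.49,4.38,4,1
box,6.09,4.5,5.08,3,1
bread,6.01,4.11,3.61,5,1
break,5.47,3.2,4.32,5,1
bright,7.63,1.74,3.49,6,1
brother,5.74,4.17,2.85,7,2
build,5.12,3.26,4.12,5,1
car,5.65,4.87,4.43,3,1
cat,5.52,4.9,4.39,3,1
chair,5.22,4.32,4.26,5,1
change,5.44,3.58,3.53,6,1
child,6.08,4.13,3.95,5,1
city,6.11,4.75,4.33,4,1
clean,3.86,3.05,4.15,5,1
clock,6.11,4.73,3.35,5,1
close,6.02,2.79,4.46,5,1
cloud,5.6,4.85,4.48,5,1
coat,4.9,4.96,4.5,4,1
coffee,5.84,4.73,3.59,6,1
cold,4.55,2.63,4.68,4,1
color,5.22,2.27,4.62,5,2
computer,5.4,4.56,2.18,8,2
cook,5.81,2.79,3.93,4,1
cool,5.24,2.87,3.63,4,1
cruel,1.86,1.48,3.51,5,1
cry,6.09,3.36,4.47,3,1
cup,5.44,4.02,4.5,3,1
dance,5.6,3.73,4.24,5,1
dark,2.05,2.12,4.55,4,1
death,1.4,1.84,3.23,5,1
delightful,7.66,2.41,1.76,10,2
die,5.97,3.52,4.66,3,1
dinner,4.22,1.85,3.63,6,2
doctor,6.3,4.13,3.53,6,2
dog,5.08,4.9,5.2,3,1
door,4.38,4.97,5,4,1
dream,4.67,2,4.36,5,1
drink,5.17,2.98,3.8,5,1
drive,5.87,3.51,3.22,5,1
eat,4.58,2.62,5.1,3,1
explain,4.79,3.21,2.65,7,1
eye,5.58,4.67,5.16,3,1
face,5.11,4.77,4.69,4,1
family,5.34,4.28,3.55,6,2
farm,5.51,4.18,4.45,4,1
fast,5.13,2.79,4.16,4,1
father,6.93,4.29,3.59,6,2
fear,2.2,1.76,4.23,4,1
feel,4.79,2.87,4.47,4,1
field,5.68,5,4.14,5,1
find,6.06,3.64,5.26,4,1
fire,4.58,3.82,4.2,4,1
fish,4.42,5,4.14,4,1
floor,4.7,4.87,4.74,5,2
flower,5.29,4.89,3.64,6,2
fly,5.17,3.66,4.66,3,1
foot,6.54,4.25,4.28,4,1
forest,4.08,5,3.23,6,1
forget,4.96,2.9,3.43,6,1
fresh,8.4,2.08,3.53,5,1
friend,5.46,4.47,3.17,6,1
fruit,6.45,4.46,2.98,5,1
funeral,1.8,2.34,3.06,7,1
game,5.36,1.82,4.68,4,1
garden,6.13,4.49,3.11,6,1
gentle,6.6,1.94,3.82,6,1
gift,5.04,4.85,4.63,4,1
give,5.16,3.09,4.1,4,1
glad,7.12,2.28,4.97,4,1
good,6.74,1.38,4.63,4,1
grow,4.98,3.28,4.08,4,1
hair,5.26,4.86,4.06,4,1
hand,4.58,3.89,4.67,4,1
happy,8.5,1.32,3.3,5,1
hard,4.64,2.93,4.25,4,1
hat,4.88,3.5,4.99,3,1
hate,1.6,1.6,4.6,4,1
heal,7.25,3.73,4.59,4,1
hear,5.37,2.89,5.27,4,1
heart,6.19,1.42,3.55,5,1
heaven,8.1,1.97,3.98,6,1
heavy,5.29,3.1,3.66,5,1
help,5.73,3.66,4.47,4,1
hold,5.6,3.08,4.08,4,1
home,4.92,4.71,4.98,4,1
hope,7.5,1.6,4.78,4,1
horrible,2.67,1.74,2.91,8,2
horse,4.51,5,4.4,5,1
hot,5.08,3.02,4.33,3,1
house,5.41,4.22,3.69,5,1
hungry,2.36,2.23,3.86,6,1
hurt,5.51,3.97,4.21,4,1
idea,3.98,1.4,5.07,4,1
job,4.63,1.74,5.22,3,1
joy,8.6,2.25,5.15,3,1
jump,6.31,3.26,5.13,4,1
keep,5.99,3.15,4.17,4,1
key,3.48,4.31,4.62,3,1
kitchen,6.5,4.26,3.65,7,1
kitten,5.5,4.38,3.76,6,1
knife,5.49,4.1,3.15,5,1
laugh,6.54,3.72,4.22,5,1
learn,4.92,3.19,3.09,5,1
leave,5.04,3.51,3.72,5,1
leg,3.54,4.1,5.38,3,1
letter,6.74,5,3.06,6,2
life,5.07,1.84,4.22,4,1
listen,5.66,3.46,3.3,6,1
live,6.27,2.86,4.53,4,1
lock,6.3,3.83,4.24,4,1
lonely,2.27,1.12,3.91,6,2
long,5.31,2.82,4.46,4,1
lose,3.73,3.02,4.06,4,1
loud,4.92,3.14,4.76,4,1
love,8.7,2.1,4.45,4,1
lovely,6.5,2.13,3.95,6,2
man,5.13,4.09,5.11,3,1
meet,6.51,3.34,4.28,4,1
milk,5.3,4.26,4.28,4,1
mind,5.26,1.69,4.66,4,1
money,5.63,2.1,3.63,5,1
moon,5.3,4.47,3.85,4,1
morning,5.81,1.73,3.11,7,1
mother,6.9,3.92,4.16,6,2
mountain,4.29,4.33,2.34,8,1
murder,1.2,2.45,4.05,6,2
muscle,5.59,4.74,3.54,6,1
music,5.3,1.66,4.39,5,1
new,4.92,2.71,4.96,3,1
nice,8.01,2.72,4.55,4,1
night,5.69,1.44,3.82,5,1
noise,5.18,2,4.89,5,1
ocean,5.4,4.57,3.77,5,1
old,4.76,3.64,5.07,3,1
open,5.89,4.02,4.12,4,1
pain,1.9,1.03,4.63,4,1
paint,4.89,3.08,4.05,5,1
paper,5.72,5,3.84,5,2
peace,7.8,1.86,4.39,5,1
pen,5.42,4.11,4.86,3,1
phone,5.33,5,3.46,5,1
picture,6.01,4.81,3.59,7,1
plate,4.57,4.39,3.74,5,1
play,4.29,3.72,4.24,4,1
pleasant,8.88,2.21,3.01,8,1
poor,2.1,1.95,4.87,4,1
problem,5.2,1.82,2.53,7,1
proud,7.36,1.21,3.92,5,1
puppy,8.3,4.43,4.1,5,1
question,5.2,2.27,2.82,8,2
quiet,6.28,2.98,4.34,5,1
rain,4.99,4.52,4.92,4,1
rainbow,5.76,4.98,3.75,7,2
read,6.06,3.65,5.1,4,1
reason,5.3,2.22,3.32,6,1
remember,4.75,3.41,2.5,8,2
return,5.61,3.16,3.05,6,1
rich,6.7,2.26,4.56,4,1
river,4.55,4.7,3.51,5,2
road,4.09,4.27,3.9,4,1
roof,5.52,4.35,5.12,4,1
room,6.24,5,4.76,4,1
run,5.05,3.38,4.43,3,1
sad,1.9,1.79,5.12,3,1
school,5.43,4.31,3.71,6,1
shadow,4.48,2.37,3.8,6,1
shoe,5.29,4.87,4.43,4,1
short,4.16,3.19,4.38,5,1
shout,6,3.19,3.34,5,1
sick,2.02,1.89,3.88,4,1
silence,5.96,1.76,2.25,7,1
sing,5.35,3.02,3.94,4,1
sister,6.74,4.85,3.95,6,2
sit,5.21,4.18,4.21,3,1
skin,5.95,4.25,4.46,4,1
sleep,4.99,3.39,3.45,5,1
slow,4.48,2.81,4.01,4,1
small,4.48,2.96,3.91,5,1
smell,4.52,1.79,3.71,5,1
smile,8,2.32,4.53,5,1
snow,5.6,4.3,4.42,4,1
soft,5.87,2.9,3.43,4,1
song,4.91,2.03,4.89,4,1
sound,5.39,1.81,4.05,5,1
speak,4.95,3.09,3.9,5,1
spoon,6.04,4.51,3.95,5,1
stand,5.15,3.25,4.35,5,1
star,4.86,4.33,3.71,4,1
start,5.49,3.28,3.98,5,1
stay,5.79,3.34,4.2,4,1
stone,5.39,4.8,4.05,5,1
stop,4.62,2.77,4.49,4,1
storm,6.51,4.72,3.98,5,1
story,5.78,2.16,3.81,5,1
street,6.65,4.68,3.83,6,1
strong,7.17,1.79,3.62,6,1
summer,6.07,1.78,3.52,6,2
sun,6.17,4.65,4.83,3,1
sunshine,8.2,4.57,2.27,8,2
sweet,6.36,2.36,3.61,5,1
swim,4.9,3.54,4.25,4,1
table,5.12,4.18,4.64,5,1
talk,6.12,2.56,4.22,4,1
tall,5.14,2.86,4.63,4,1
taste,4.8,1.91,3.2,5,1
tea,5.43,4.96,4.12,3,1
teach,5.51,3.64,3.9,5,1
teacher,6.11,3.94,2.68,7,2
terrible,2.55,2.19,1.85,8,2
tired,1.9,1.95,3.76,5,1
tooth,5.81,4.38,4.57,5,1
touch,5.43,2.74,4.17,5,1
train,4.61,4.4,4.22,5,1
travel,5.88,2.65,3.39,6,1
tree,5.82,4.63,4.71,4,1
truth,5.42,1.3,3.13,5,1
ugly,3.21,1.52,4.41,4,1
understand,5.69,3.39,1.51,10,1
village,5.66,4.65,3.08,7,1
visit,5.47,3.22,4.33,5,1
voice,5.19,1.51,3.73,5,1
walk,5.31,2.21,4.28,4,1
wall,6.29,4.69,4.91,4,1
war,1.7,1.73,5.12,3,1
warm,7.88,1,5.08,4,1
wash,4.83,2.68,4.47,4,1
watch,5.12,2.88,3.6,5,1
water,5.17,4.34,3.74,5,2
weak,2.77,1.62,5.07,4,1
whisper,6.9,3.77,2.73,7,2
wind,5.99,4.17,4.19,4,1
window,5.64,4.28,3.31,6,1
winter,5.21,2.34,3.87,6,2
woman,6.62,4.27,3.45,5,1
wonderful,9,1.37,1.77,9,2
word,4.4,2.43,4.25,4,1
write,5.85,2.84,3.8,5,1
young,6.1,2.5,4.08,5,1
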