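Word,Conc.M
this,2.26
these,2.19
that,2.04
those,2.15
she,4.04
he,4.08
they,3.43
her,3.95
him,4.16
them,3.47
it,2.49
we,3.55
you,4.11
i,4.05
tomato,5
idea,1.62
sound,3.7
visit,3.92
elephant,4.93
lounge,3.5
great,1.64
super,2.0
spectacular,3.0
baby,4.9
dog,4.85
cat,4.86
house,4.95
freedom,1.47
love,2.07
truth,1.96
justice,1.45
water,5
tree,5
story,2.9
video,4.5
photo,4.8
picture,4.52
people,4.0
world,3.4
thing,3.6
way,2.0
time,2.75
secret,2.1
reason,1.78
moment,2.87
life,2.5
change,2.35
answer,2.6
question,3.07
problem,2.0
news,3.2
headline,4.1
word,3.9
letter,4.7
book,4.9
school,4.7
teacher,4.6
child,4.6
woman,4.8
man,4.8
girl,4.9
boy,4.9
family,4.0
friend,3.8
money,4.55
job,3.9
work,3.5
home,4.3
city,4.3
street,4.7
car,4.9
food,4.9
happy,2.56
sad,2.38
beautiful,2.2
amazing,1.8
incredible,1.6
wonderful,1.9
perfect,2.0
simple,2.3
easy,2.2
hard,3.0
big,3.6
small,3.6
old,3.1
new,2.4
young,3.2
good,2.2
bad,2.3
right,2.4
wrong,2.1
true,2.0
real,2.2
whole,2.5
full,3.1
got,3.0
get,2.9
go,3.3
make,3.2
take,3.4
give,3.3
see,3.8
watch,4.0
look,3.7
find,2.9
know,1.9
think,1.8
feel,2.3
want,2.0
need,2.1
say,3.3
tell,3.2
ask,3.0
show,3.4
speak,3.6
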