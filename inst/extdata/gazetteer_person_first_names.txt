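aaron
abigail
adam
alex
alexander
alexandra
alice
amanda
amy
andrew
angela
anna
anthony
ashley
barack
barbara
benjamin
bernie
beyonce
bill
bob
brandon
brian
carlos
carol
catherine
charles
charlotte
chris
christina
christopher
claire
daniel
david
deborah
dennis
diana
donald
donna
dorothy
edward
elizabeth
ellen
emily
emma
eric
ethan
eva
frank
gary
george
grace
gregory
hannah
harry
heather
helen
henry
hillary
jack
jacob
james
jane
janet
jason
jennifer
jeremy
jessica
joan
joe
john
jonathan
jordan
jose
joseph
joshua
juan
judith
julia
julie
justin
kamala
karen
katherine
kathleen
keith
kelly
kevin
kimberly
kyle
larry
laura
lauren
lawrence
linda
lisa
louis
madeleine
malala
margaret
maria
marianne
marie
mark
martha
martin
mary
matthew
megan
melissa
michael
michelle
mitt
nancy
nathan
nicholas
nicole
noah
olivia
oprah
pamela
patricia
patrick
paul
peter
philip
rachel
raymond
rebecca
richard
robert
ronald
rosa
russell
ruth
ryan
samantha
samuel
sandra
sarah
scott
sean
serena
sharon
sophia
stephanie
stephen
steven
susan
taylor
teresa
terry
thomas
timothy
tyler
victoria
vincent
virginia
walter
wayne
william
zach
zachary
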