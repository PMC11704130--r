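aclu
airbnb
amazon
apple
army
bbc
cia
cnn
congress
disney
exxon
facebook
fbi
fda
fifa
google
goldman
greenpeace
harvard
ibm
ikea
instagram
interpol
mcdonalds
microsoft
mit
monsanto
nasa
nato
navy
nbc
netflix
nike
nsa
nypd
olympics
oxfam
oxford
pentagon
pepsi
pixar
playstation
reddit
samsung
senate
sony
spacex
stanford
starbucks
target
tesla
twitter
ucla
un
unesco
unicef
upworthy
walmart
who
wikipedia
yale
youtube
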