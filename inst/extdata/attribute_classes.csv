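name,class
pop.total,extensive
occ.units,extensive
pop.male,intensive
pop.u20,intensive
pop.20.64,intensive
pop.o64,intensive
pop.married,intensive
pop.white,intensive
pop.black,intensive
pop.native,intensive
pop.asian,intensive
pop.pacific,intensive
pop.latino,intensive
occupants.1.5,intensive
rent.35.income,intensive
pop.single.hh,intensive
hh.size,intensive
no.school,intensive
poverty,intensive
med.income,intensive
pop.no.insur,intensive
pop.unempl,intensive
lan.english,intensive
lan.spanish,intensive
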