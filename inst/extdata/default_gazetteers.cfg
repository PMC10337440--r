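# pain gazetteer config
[negation_triggers]
no
not
denies
denied
without
nil
[experiencer_triggers]
mother
father
wife
husband
son
daughter
friend
family
carer
staff
brother
sister
[hypothetical_triggers]
fear of
afraid
if
would be
in case
risk of
sore thumb
[emotional_triggers]
relationship
partner
boyfriend
girlfriend
divorce
breakup
marriage
[anatomy_map]
head	head
chest	chest
back	back
abdomen	abdomen
abdominal	abdomen
pelvis	abdomen
pelvic	abdomen
stomach	abdomen
tummy	abdomen
belly	abdomen
neck	neck
shoulder	shoulder
arm	arm
leg	leg
knee	knee
hip	hip
hand	hand
foot	foot
feet	foot
[anatomy_compounds]
headache	head
headaches	head
backache	back
backaches	back
heartburn	chest
migraine	head
migraines	head
lumbago	back
stomachache	abdomen
stomachaches	abdomen
mittelschmerz	abdomen
[character_descriptors]
shooting
throbbing
burning
severe
constant
sharp
dull
aching
stabbing
neuropathic
uropathic
colicky
[management_medication_triggers]
painkiller
painkillers
analgesia
analgesic
analgesics
paracetamol
ibuprofen
codeine
morphine
tramadol
pain relief medication
[management_other_triggers]
physiotherapy
pain clinic
massage
[inanimate_referents]
things
marks
incense
toast
candle
candles
door
fire
rubbish
paper
food
wood
calories
[options]
negation_window	6
proximity_window	3
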