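# pain lexicon config
[patterns]
%pain%	Pain
%ache	Ache
%aches	Ache
achin%	Ache
sore%	Sore
%algesi%	Algesia
%algia%	Algia
%burn%	Burn
colic%	Colic
cramp%	Cramp
%dynia%	Dynia
hurt%	Hurt
rheumati%	Rheumatic
sciati%	Sciatic
spasm%	Spasm
tender%	Tender
[full_terms]
mittelschmerz	Mittelschmerz
lumbago	Lumbago
migraine	Migraine
[exclusions]
paint
painting
paints
painted
spain
attached
attaches
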