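label	phone_sequence	duration
a	a-#	150
pa	p-@-a-#	200
pi	p-@-i-#	200
pu	p-@-u-#	200
ta	t-@-a-#	200
ti	t-@-i-#	200
tu	t-@-u-#	200
apa	a-p-@-a-#	300
ata	a-t-@-a-#	300
ipi	i-p-@-i-#	300
iti	i-t-@-i-#	300
upu	u-p-@-u-#	300
utu	u-t-@-u-#	300
papa	p-@-a-p-@-a-#	350
pata	p-@-a-t-@-a-#	350
patu	p-@-a-t-@-u-#	350
pipi	p-@-i-p-@-i-#	350
pita	p-@-i-t-@-a-#	350
tata	t-@-a-t-@-a-#	350
tatu	t-@-a-t-@-u-#	350
tuti	t-@-u-t-@-i-#	350
apata	a-p-@-a-t-@-a-#	450
apiti	a-p-@-i-t-@-i-#	450
iputu	i-p-@-u-t-@-u-#	450
utatu	u-t-@-a-t-@-u-#	450
patata	p-@-a-t-@-a-t-@-a-#	500
patati	p-@-a-t-@-a-t-@-i-#	500
tapatu	t-@-a-p-@-a-t-@-u-#	500
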