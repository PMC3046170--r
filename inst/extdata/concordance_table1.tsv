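authority	legacy_term	modern_abbrev	note
hatcher1901	infradiapophyseal cavity	cdf
hatcher1901	prediapophyseal cavity	prcdf
hatcher1901	postdiapophyseal cavity	pocdf
hatcher1901	supradiapophyseal cavity	sdf
hatcher1901	infraprezygapophyseal cavity	cprf
hatcher1901	supraprezygapophyseal cavity	sprf
hatcher1901	infrapostzygapophyseal cavity	cpof
hatcher1901	suprapostzygapophyseal cavity	spof
osborn_mook1921	infradiapophyseal cavity	cdf
osborn_mook1921	infraprezygapophyseal cavity	prcdf
osborn_mook1921	infrapostzygapophyseal cavity	pocdf
osborn_mook1921	supraprezygapophyseal cavity	prsdf
osborn_mook1921	suprapostzygapophyseal cavity	posdf
osborn_mook1921	supradiapophyseal cavity	sdf1
osborn_mook1921	postspinal cavity	spof
welles1984	medial chonos	cdf
welles1984	anterior chonos	prcdf
welles1984	posterior chonos	pocdf
welles1984	prechonos	cprf
welles1984	prespinal chonos	sprf
welles1984	postchonos	cpof
welles1984	postspinal chonos	spof
bonaparte1999	central infradiapophyseal cavity	cdf	translated from the Spanish
bonaparte1999	anterior infradiapophyseal cavity	prcdf	translated from the Spanish
bonaparte1999	posterior infradiapophyseal cavity	pocdf	translated from the Spanish; cell joined with infrapostzygapophyseal depression
bonaparte1999	infrapostzygapophyseal depression	pocdf	translated from the Spanish; cell joined with posterior infradiapophyseal cavity
bonaparte1999	postparapophyseal fossa	prpadf	translated from the Spanish; same term also maps to cpaf
bonaparte1999	depression lateral to the diapophyseal lamina	sdf	translated from the Spanish
bonaparte1999	depression of the diapophyseal lamina	sdf1	translated from the Spanish
bonaparte1999	postparapophyseal fossa	cpaf	translated from the Spanish; same term also maps to prpadf
bonaparte1999	circumneural cavity	cprf	translated from the Spanish; cell joined with supraneural cavity; distinction between the two unclear
bonaparte1999	supraneural cavity	cprf	translated from the Spanish; cell joined with circumneural cavity; distinction between the two unclear
bonaparte1999	prespinal cavity	sprf	translated from the Spanish
bonaparte1999	circumneural cavity	cpof	translated from the Spanish; cell joined with supraneural cavity; distinction between the two unclear
bonaparte1999	supraneural cavity	cpof	translated from the Spanish; cell joined with circumneural cavity; distinction between the two unclear
bonaparte1999	postspinal cavity	spof	translated from the Spanish
harris2006	infradiapophyseal fossa	cdf	same term also maps to pacdf
harris2006	cranial infradiapophyseal fossa	prcdf	same term also maps to prpadf
harris2006	caudal infradiapophyseal fossa	pocdf
harris2006	infradiapophyseal fossa	pacdf	same term also maps to cdf
harris2006	cranial infradiapophyseal fossa	prpadf	same term also maps to prcdf
harris2006	parazygapophyseal fossa	sdf
harris2006	paraspinous fossa	posdf
harris2006	infraparapophyseal fossa	cpaf
harris2006	cranial infrazygapophyseal fossa	cprf
harris2006	prespinous fossa	sprf	cell joined with cranial elastic ligament fossa
harris2006	cranial elastic ligament fossa	sprf	cell joined with prespinous fossa
harris2006	caudal infrazygapophyseal fossa	cpof
harris2006	postspinous fossa	spof	cell joined with caudal elastic ligament fossa
harris2006	caudal elastic ligament fossa	spof	cell joined with postspinous fossa
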