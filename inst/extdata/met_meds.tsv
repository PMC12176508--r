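drug	site
palbociclib	breast
ribociclib	breast
fulvestrant	breast
sacituzumab govitecan	breast
regorafenib	gastrointestinal
trifluridine-tipiracil	gastrointestinal
ramucirumab	gastrointestinal
abiraterone	genitourinary
enzalutamide	genitourinary
cabazitaxel	genitourinary
osimertinib	lung
lorlatinib	lung
sotorasib	lung
temozolomide	nervous_system
lomustine	nervous_system
ibrutinib	hematologic
venetoclax	hematologic
pomalidomide	hematologic
pazopanib	sarcoma
trabectedin	sarcoma
eribulin	sarcoma
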