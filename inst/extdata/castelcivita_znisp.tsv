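broad_category	zooms_id	Mousterian	Uluzzian	Protoaurignacian
Equid	Equus	3	338	107
Cervidae	Cervid	118	107	23
Cervidae	Capreolus capreolus	1	12	0
Artiodactyla	Cervid/Rupicapra	2	0	0
Bos/Bison	Bos/Bison	13	96	47
Caprine	Capra sp.	21	14	4
Caprine	Rupicapra	8	52	5
Rhinoceros	Rhinoceros	2	0	0
Cervidae	Unidentified Cervid	15	90	1
Caprine	Unidentified Caprine	1	3	2
Artiodactyla	Artiodactyla	0	1	0
Sus sp.	Sus sp.	2	13	0
Carnivore	Ursus sp.	3	2	0
Carnivore	Canid	1	1	0
Carnivore	Felis/Lynx/Ursus	2	0	0
Carnivore	Panthera/Crocuta	0	0	1
Carnivore	Carnivora	0	3	0
Fail	Fail	18	108	23
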