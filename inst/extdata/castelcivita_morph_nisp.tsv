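# Morphological NISP per ZooMS category and cultural complex, transcribed
# from the published assemblage table. Several printed cells are
# typographically ambiguous; this transcription is best-effort and intended
# only for association (rank) comparisons, not for exact arithmetic.
# "-" cells (category absent from the morphological record) are stored as 0.
zooms_id	Mousterian	Uluzzian	Protoaurignacian
Equus	33	73	10
Cervid	144	69	7
Capreolus capreolus	29	34	2
Cervid/Rupicapra	0	0	0
Bos/Bison	14	17	6
Capra sp.	53	12	1
Rupicapra	85	25	0
Rhinoceros	1	0	0
Unidentified Cervid	17	5	0
Unidentified Caprine	0	0	0
Artiodactyla	0	0	0
Sus sp.	7	8	7
Ursus sp.	1	5	0
Canid	0	5	0
Felis/Lynx/Ursus	0	5	0
Panthera/Crocuta	15	12	0
Carnivora	0	7	0
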