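gene	species	state	quality
BEST2	zebra_finch	absent	gapless
BEST2	bengalese_finch	unknown	fragmented
BEST2	medium_ground_finch	unknown	fragmented
BEST2	tit	present	gappy
BEST2	starling	present	gappy
BEST2	chicken	present	gappy
BEST2	human	present	gappy
CATSPER2	zebra_finch	absent	gapless
CATSPER2	tit	absent	gappy
CATSPER2	starling	absent	gappy
CATSPER2	manakin	absent	gappy
CATSPER2	budgie	present	gappy
CATSPER2	chicken	present	gappy
CATSPER2	human	present	gappy
BEST4	zebra_finch	absent	gapless
BEST4	bengalese_finch	absent	gappy
BEST4	tit	absent	gappy
BEST4	starling	absent	gappy
BEST4	manakin	absent	gappy
BEST4	budgie	present	gappy
BEST4	chicken	present	gappy
BEST4	human	present	gappy
CLCA1	zebra_finch	absent	gapless
CLCA1	manakin	absent	gappy
CLCA1	tit	absent	gappy
CLCA1	starling	absent	gappy
CLCA1	budgie	present	gappy
CLCA1	eagle	present	gappy
CLCA1	chicken	present	gappy
CLCA1	guinea_fowl	present	gappy
CLCA1	tinamou	present	gappy
CLCA1	human	present	gappy
CLCA2	zebra_finch	absent	gapless
CLCA2	manakin	absent	gappy
CLCA2	tit	absent	gappy
CLCA2	starling	absent	gappy
CLCA2	budgie	present	gappy
CLCA2	eagle	present	gappy
CLCA2	chicken	present	gappy
CLCA2	guinea_fowl	present	gappy
CLCA2	tinamou	present	gappy
CLCA2	human	present	gappy
CLCA4	zebra_finch	absent	gapless
CLCA4	manakin	absent	gappy
CLCA4	tit	absent	gappy
CLCA4	starling	absent	gappy
CLCA4	budgie	present	gappy
CLCA4	eagle	present	gappy
CLCA4	chicken	present	gappy
CLCA4	guinea_fowl	present	gappy
CLCA4	tinamou	present	gappy
CLCA4	human	present	gappy
CATSPERG	zebra_finch	absent	gapless
CATSPERG	chicken	absent	gapless
CATSPERG	ostrich	present	gappy
CATSPERG	emu	present	gappy
CATSPERG	human	present	gappy
CATSPER1	zebra_finch	absent	gapless
CATSPER1	chicken	absent	gapless
CATSPER1	ostrich	present	gappy
CATSPER1	emu	present	gappy
CATSPER1	human	present	gappy
CATSPER4	zebra_finch	absent	gapless
CATSPER4	chicken	absent	gapless
CATSPER4	ostrich	present	gappy
CATSPER4	emu	present	gappy
CATSPER4	human	present	gappy
CLIC1	zebra_finch	absent	fragmented
CLIC1	chicken	absent	fragmented
CLIC1	kiwi	present	gappy
CLIC1	alligator	present	gappy
CLIC1	human	present	gappy
CACNG6	zebra_finch	absent	gapless
CACNG6	chicken	absent	gapless
CACNG6	ostrich	absent	gappy
CACNG6	emu	absent	gappy
CACNG6	kiwi	absent	gappy
CACNG6	tinamou	absent	gappy
CACNG6	alligator	present	gappy
CACNG6	human	present	gappy
LRRC8E	zebra_finch	absent	gapless
LRRC8E	chicken	absent	gapless
LRRC8E	ostrich	absent	gappy
LRRC8E	emu	absent	gappy
LRRC8E	kiwi	absent	gappy
LRRC8E	tinamou	absent	gappy
LRRC8E	alligator	present	gappy
LRRC8E	human	present	gappy
SCN7A	zebra_finch	absent	gapless
SCN7A	chicken	absent	gapless
SCN7A	ostrich	absent	gappy
SCN7A	emu	absent	gappy
SCN7A	alligator	absent	gappy
SCN7A	lizard	absent	gappy
SCN7A	turtle	absent	gappy
SCN7A	xenopus	absent	gappy
SCN7A	human	present	gappy
SCN7A	platypus	present	gappy
SCN7A	opossum	present	gappy
CATSPERZ	zebra_finch	absent	gapless
CATSPERZ	chicken	absent	gapless
CATSPERZ	ostrich	absent	gappy
CATSPERZ	emu	absent	gappy
CATSPERZ	alligator	absent	gappy
CATSPERZ	lizard	absent	gappy
CATSPERZ	turtle	absent	gappy
CATSPERZ	xenopus	absent	gappy
CATSPERZ	human	present	gappy
CATSPERZ	platypus	present	gappy
CATSPERZ	opossum	present	gappy
CLCNK-duplication	zebra_finch	absent	gapless
CLCNK-duplication	chicken	absent	gapless
CLCNK-duplication	ostrich	absent	gappy
CLCNK-duplication	emu	absent	gappy
CLCNK-duplication	alligator	absent	gappy
CLCNK-duplication	lizard	absent	gappy
CLCNK-duplication	turtle	absent	gappy
CLCNK-duplication	xenopus	absent	gappy
CLCNK-duplication	human	present	gappy
CLCNK-duplication	platypus	present	gappy
CLCNK-duplication	opossum	present	gappy
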