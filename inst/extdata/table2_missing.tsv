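gene	family	category	chicken_present
BEST2	chloride	Missing in finches	TRUE
CATSPER2	calcium	Missing in Passeriformes	FALSE
BEST4	chloride	Missing in Passeriformes	TRUE
CLCA1	chloride	Missing in Passeriformes	TRUE
CLCA2	chloride	Missing in Passeriformes	TRUE
CLCA4	chloride	Missing in Passeriformes	FALSE
CATSPERG	calcium	Missing in Neognathae	FALSE
CATSPER1	calcium	Missing in Neognathae	FALSE
CATSPER4	calcium	Missing in Neognathae	FALSE
CLIC1	chloride	Missing in Neognathae	FALSE
CACNG6	calcium	Missing in all birds	FALSE
LRRC8E	chloride	Missing in all birds	FALSE
SCN7A	sodium	Unique to mammals	FALSE
CATSPERZ	calcium	Unique to mammals	FALSE
CLCNK-duplication	chloride	Unique to mammals	FALSE
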