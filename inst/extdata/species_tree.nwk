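((((((((((zebra_finch,(bengalese_finch,medium_ground_finch)inner_finches)finches,(tit,starling)tits_starlings)core_passerines,manakin)Passeriformes,budgie)Psittacopasserae,(eagle,falcon)raptors)Neoaves,((chicken,quail)phasianids,guinea_fowl)Galliformes)Neognathae,((ostrich,emu)big_ratites,(kiwi,tinamou)kiwi_tinamou)Palaeognathae)Aves,((alligator,turtle)archosaur_turtle,lizard)Reptilia)Sauropsida,(human,(platypus,opossum)basal_mammals)Mammalia)Amniota,xenopus)Tetrapoda;
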