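network,rank,food,integrated_centrality,degree,betweenness,eigenvector,closeness,strength,role
non_diabetic_specific,1,Cuttlefish,3.510,6,0.173,1.000,1.968,1.393,primary_hub
non_diabetic_specific,2,Cheese and Pizza/Hamburgers,3.423,5,0.377,0.754,2.169,1.067,hub_food
non_diabetic_specific,3,Mushrooms,3.323,5,0.260,0.870,2.021,1.166,hub_food
non_diabetic_specific,4,Poultry,2.662,4,0.156,0.692,1.637,0.916,bridge
non_diabetic_specific,5,Non-Native Fruit,2.536,4,0.294,0.184,1.770,0.832,bridge
diabetic_specific,1,Breads/Spreads,4.073,5,0.122,1.000,1.442,1.146,primary_hub
diabetic_specific,2,Dumplings and Tteokguk,3.319,4,0.151,0.428,1.815,0.852,hub_food
diabetic_specific,3,Eggs,2.496,2,0.119,0.594,1.612,0.463,hub_food
diabetic_specific,4,Poultry,2.432,2,0.127,0.443,1.769,0.458,connector
diabetic_specific,5,Salt-Fermented Food,2.221,3,0.061,0.172,1.303,0.636,connector
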