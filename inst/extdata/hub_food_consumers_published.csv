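network,group_n,food,mean_consumption,sd_consumption,median_consumption,n_consumers,consumer_pct,degree,betweenness,closeness,eigenvector,strength
non_diabetic,15712,Total rice,2.8,0.7,3,12066,76.8,24,0.156,2.742,0.953,6.42
non_diabetic,15712,Vegetable dishes,0.5,0.7,0.3,11784,75.0,23,0.170,2.647,1,6.57
non_diabetic,15712,Mushrooms,0.1,0.2,0,11791,75.0,20,0.061,2.475,0.964,5.40
non_diabetic,15712,Processed meat/seafood,0.1,0.1,0,8174,52.0,16,0.093,2.572,0.681,3.84
non_diabetic,15712,Non-native fruit,0.1,0.2,0,11988,76.3,16,0.089,2.547,0.661,3.92
non_diabetic,15712,Sliced raw fish and eel,0,0.1,0,7861,50.0,15,0.035,2.423,0.747,3.88
non_diabetic,15712,Shellfish,0.1,0.2,0,7996,50.9,15,0.017,2.326,0.781,4.03
non_diabetic,15712,Cheese and pizza/hamburgers,0,0.1,0,3866,24.6,14,0.043,2.439,0.645,3.42
non_diabetic,15712,Starch,0,0.1,0,8211,52.3,14,0.090,2.489,0.622,3.32
non_diabetic,15712,Beef,0.1,0.2,0,12049,76.7,14,0,2.411,0.727,3.59
diabetic,953,Total rice,2.9,0.7,3,721,75.7,25,0.163,2.751,1,6.44
diabetic,953,Vegetable dishes,0.5,0.8,0.3,715,75.0,22,0.236,2.607,0.933,6.05
diabetic,953,Processed meat/seafood,0.1,0.1,0,495,51.9,18,0.056,2.474,0.796,4.66
diabetic,953,Mushrooms,0.1,0.2,0,492,51.6,16,0.047,2.265,0.829,4.32
diabetic,953,Tofu/bean sprouts,0.4,0.5,0.3,715,75.0,14,0.063,2.254,0.549,3.56
diabetic,953,Shellfish,0.1,0.2,0,483,50.7,14,0.022,2.341,0.689,3.54
diabetic,953,Non-native fruit,0.1,0.2,0,490,51.4,14,0.075,2.308,0.617,3.47
diabetic,953,Beef,0.1,0.2,0,716,75.1,13,0.027,2.391,0.679,3.35
diabetic,953,Sliced raw fish and eel,0,0.1,0,478,50.2,13,0.044,2.292,0.6,3.29
diabetic,953,Starch,0,0.1,0,490,51.4,12,0.042,2.291,0.57,2.88
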