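"diet","ingredient","inclusion"
"CTRL","Fishmeal super prime",15
"CTRL","Fishmeal",5
"CTRL","Fish protein hydrolysate",3
"CTRL","Poultry meal",15
"CTRL","Poultry blood meal",3
"CTRL","Feathermeal hydrolysate",5
"CTRL","Microbial meal",4
"CTRL","Corn gluten meal",8
"CTRL","Guar korma",5
"CTRL","Sunflower meal",3
"CTRL","Wheat meal",13.48
"CTRL","Whole peas",5.5
"CTRL","Vitamin and mineral premix",1
"CTRL","Choline chloride",0.2
"CTRL","Antioxidant",0.2
"CTRL","Yttrium oxide",0.02
"CTRL","Rapeseed lecithin",0.5
"CTRL","Fish oil",4.45
"CTRL","Salmon oil",8.65
"ORG","Fishmeal super prime",15
"ORG","Brewer's yeast",5
"ORG","Arthrospira platensis",5
"ORG","Potato protein concentrate",8.9
"ORG","Pea protein concentrate",11
"ORG","Wheat gluten",11
"ORG","Guar korma",9.5
"ORG","Rapeseed meal",4.5
"ORG","Wheat meal",7.58
"ORG","Whole peas",5.5
"ORG","Vitamin and mineral premix",1
"ORG","Choline chloride",0.2
"ORG","Antioxidant",0.2
"ORG","Mono-calcium phosphate",1.1
"ORG","Yttrium oxide",0.02
"ORG","Rapeseed lecithin",0.5
"ORG","Fish oil",7
"ORG","Rapeseed oil",7
"ECO","Fishmeal",5
"ECO","Fish protein hydrolysate",3
"ECO","Poultry meal",20
"ECO","Poultry blood meal",5
"ECO","Feathermeal hydrolysate",10
"ECO","Microbial meal",4
"ECO","Corn gluten meal",5.7
"ECO","Guar korma",5
"ECO","Sunflower meal",6
"ECO","Wheat meal",12.63
"ECO","Whole peas",5.5
"ECO","Vitamin and mineral premix",1
"ECO","Choline chloride",0.2
"ECO","Antioxidant",0.2
"ECO","Mono-calcium phosphate",1.65
"ECO","L-Lysine",0.5
"ECO","DL-Methionine",0.05
"ECO","Yttrium oxide",0.02
"ECO","Algae meal (Schizochytrium)",1.3
"ECO","Rapeseed lecithin",0.5
"ECO","Fish oil",4.45
"ECO","Salmon oil",8.3
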