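"ingredient","gwp_factor"
"Fishmeal super prime",1132.0029
"Fishmeal",1345.3576
"Fish protein hydrolysate",2467.2146
"Poultry meal",1490.7617
"Poultry blood meal",1709.0901
"Feathermeal hydrolysate",1800.0464
"Microbial meal",4456.2861
"Brewer's yeast",1386.6655
"Arthrospira platensis",6186.6655
"Potato protein concentrate",2932.2646
"Pea protein concentrate",2610.6641
"Wheat gluten",2510.6641
"Corn gluten meal",1149.4153
"Guar korma",1500.022
"Rapeseed meal",767.9989
"Sunflower meal",880.0279
"Wheat meal",675.3719
"Whole peas",645.2254
"Vitamin and mineral premix",2026.4046
"Choline chloride",2505.2809
"Antioxidant",2505.2809
"Mono-calcium phosphate",1758.1137
"L-Lysine",4035.4689
"DL-Methionine",3503.5469
"Yttrium oxide",8000.5281
"Algae meal (Schizochytrium)",5592.2191
"Rapeseed lecithin",1813.2023
"Fish oil",2212.7
"Salmon oil",1080.6405
"Rapeseed oil",1561.3317
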