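"diet","amino_acid","class","mg_per_g_dm"
"CTRL","Arginine","essential",31.2
"ORG","Arginine","essential",33.79
"ECO","Arginine","essential",33.01
"CTRL","Histidine","essential",11.26
"ORG","Histidine","essential",11.6
"ECO","Histidine","essential",10.97
"CTRL","Lysine","essential",26.33
"ORG","Lysine","essential",29.11
"ECO","Lysine","essential",27.86
"CTRL","Threonine","essential",23.82
"ORG","Threonine","essential",21.23
"ECO","Threonine","essential",24.76
"CTRL","Isoleucine","essential",21.86
"ORG","Isoleucine","essential",24.23
"ECO","Isoleucine","essential",22.08
"CTRL","Leucine","essential",39.16
"ORG","Leucine","essential",38.54
"ECO","Leucine","essential",39.47
"CTRL","Valine","essential",25.84
"ORG","Valine","essential",26.66
"ECO","Valine","essential",27.77
"CTRL","Methionine","essential",8.61
"ORG","Methionine","essential",10.27
"ECO","Methionine","essential",10.31
"CTRL","Phenylalanine","essential",22.78
"ORG","Phenylalanine","essential",25.25
"ECO","Phenylalanine","essential",23.66
"CTRL","Cystine","nonessential",8.42
"ORG","Cystine","nonessential",8.93
"ECO","Cystine","nonessential",10.94
"CTRL","Tyrosine","nonessential",15.91
"ORG","Tyrosine","nonessential",19.91
"ECO","Tyrosine","nonessential",18.17
"CTRL","Aspartic acid + asparagine","nonessential",38.34
"ORG","Aspartic acid + asparagine","nonessential",44.84
"ECO","Aspartic acid + asparagine","nonessential",37.48
"CTRL","Glutamic acid + glutamine","nonessential",71.44
"ORG","Glutamic acid + glutamine","nonessential",94.45
"ECO","Glutamic acid + glutamine","nonessential",70.44
"CTRL","Alanine","nonessential",29.29
"ORG","Alanine","nonessential",24.96
"ECO","Alanine","nonessential",28.91
"CTRL","Glycine","nonessential",33.14
"ORG","Glycine","nonessential",27.15
"ECO","Glycine","nonessential",34.78
"CTRL","Proline","nonessential",30.36
"ORG","Proline","nonessential",31.4
"ECO","Proline","nonessential",33.61
"CTRL","Serine","nonessential",25.02
"ORG","Serine","nonessential",25.13
"ECO","Serine","nonessential",30.65
"CTRL","Taurine","nonessential",1.95
"ORG","Taurine","nonessential",0.97
"ECO","Taurine","nonessential",1.64
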