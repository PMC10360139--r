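cell_line,alpha_x,beta_x,alpha_p,beta_p,let_d_kev_um,photon_source,assay,oxygenation,source_tag
SYN001,0.282939588622925,0.0403706609460403,0.365124858025832,0.044702407524419,9.9,6 MV,clonogenic,normoxic,synthetic
SYN002,0.271472480072553,0.0554086593788359,0.364569399347687,0.0229958084649254,2.6,6 MV,clonogenic,normoxic,synthetic
SYN003,0.354888968529288,0.0232512052433204,0.475440544243088,0.0216134187103547,9.9,6 MV,clonogenic,normoxic,synthetic
SYN004,0.2103742069537,0.0316040582020281,0.37117896693726,0.00263547448989943,2.6,6 MV,clonogenic,normoxic,synthetic
SYN005,0.462716488402038,0.0531116406651397,0.467408809277989,0.0282014632643317,2.6,6 MV,clonogenic,normoxic,synthetic
SYN006,0.164888369466385,0.0149348818211482,0.204246622832519,0.0131139478083857,2.6,6 MV,clonogenic,normoxic,synthetic
SYN007,0.201849734587422,0.0279191867511732,0.248795464635903,0.01670782464363,2.6,6 MV,clonogenic,normoxic,synthetic
SYN008,0.248443017929131,0.0364957052327008,0.510113156211949,0.0214795876522663,9.9,6 MV,clonogenic,normoxic,synthetic
SYN009,0.34912560767654,0.0522103868856592,0.326897531426063,0.0406695698095611,1.2,6 MV,clonogenic,normoxic,synthetic
SYN010,0.142127443432095,0.034886953897409,0.250753130314259,0.0145148127389514,2.6,6 MV,clonogenic,normoxic,synthetic
SYN011,0.123079958917443,0.0363017332597534,0.210110665821522,0.0550868266245204,9.9,6 MV,clonogenic,normoxic,synthetic
SYN012,0.356697904288412,0.0430014428056682,0.298079295928414,0.0973988957726617,1.2,6 MV,clonogenic,normoxic,synthetic
SYN013,0.393806907161838,0.0792184052400082,0.491989767968007,0.0445502643724352,2.6,6 MV,clonogenic,normoxic,synthetic
SYN014,0.178536084140047,0.0350529075883544,0.236663178408084,0.031428793223152,2.6,6 MV,clonogenic,normoxic,synthetic
SYN015,0.252992431306085,0.0369512423245654,0.279904341976356,0.0209560644402589,2.6,6 MV,clonogenic,normoxic,synthetic
SYN016,0.305348518023747,0.0835062477915373,0.288549770168281,0.036324014281969,1.2,6 MV,clonogenic,normoxic,synthetic
SYN017,0.35344365671015,0.035423607587356,0.328987487037688,0.0384223536722223,1.2,6 MV,clonogenic,normoxic,synthetic
SYN018,0.490437667447281,0.0677742557862234,0.423934310349373,0.101470056373707,2.6,6 MV,clonogenic,normoxic,synthetic
SYN019,0.24308440906927,0.0167176490516573,0.183173252797111,0.0217158072382338,1.2,6 MV,clonogenic,normoxic,synthetic
SYN020,0.594093172045318,0.0663897939688972,0.622397597919685,0.0457632294022923,2.6,6 MV,clonogenic,normoxic,synthetic
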