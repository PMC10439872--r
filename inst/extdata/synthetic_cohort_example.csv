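id,arm,PAS,IOP_post,age,gender,spherical_equivalent,UCVA,BCVA,IOP,cataract_present,CT_1,CT_2,CT_3,CT_4,CT_5,CT_6,CT_7,CT_8,CT_9,CT_10,CT_11,CT_12,CT_13,AL,ACD,LV,ICurv_nasal,ICurv_temporal,IT750_nasal,IT750_temporal,AOD500_90,AOD750_90,TISA500_90,TISA750_90,AOD500_270,AOD750_270,TISA500_270,TISA750_270,Shaffer_90,Shaffer_270
P0001,LE,FALSE,18.3168,70.0693,1,0.774084,0.0216912,0.78178,22.7524,0,204.995,241.367,264.743,205.502,177.104,289.386,194.316,313.786,244.737,259.512,247.231,296.075,232.504,22.759,2.51359,0.771785,0.239936,0.285823,0.399072,0.41547,0.0649258,0.139561,0.0273708,0.0576407,0.109737,0.154397,0.0205871,0.0823779,0,1
P0002,LPI,FALSE,22.6161,51.7429,0,0.311412,0.0988454,0.916428,26.2528,1,274.945,288.156,282.43,335.603,334.354,264.772,240.03,357.632,375.56,287.798,294.073,251.636,257.951,23.8516,2.36456,0.849945,0.288383,0.131354,0.426033,0.418524,0.0770537,0.153818,0.0259903,0.0652104,0.0813616,0.159328,0.0293292,0.0660924,1,1
P0003,LE,FALSE,18.2885,65.7021,1,0.942602,0.01,0.779834,22.5209,1,221.288,247.17,301.84,213.335,237.406,246.145,241.894,262.387,275.032,284.19,289.193,223.292,285.176,23.4154,2.8089,0.78058,0.239189,0.243648,0.445985,0.470305,0.0655228,0.119567,0.0262026,0.0405047,0.114235,0.135692,0.0368352,0.0596045,1,1
P0004,LPI,FALSE,23.8695,63.137,1,0.391406,0.467775,1.0263,24.098,0,250.589,224.396,204.739,179.636,269.396,195.38,253.539,266.417,227.538,189.306,252.392,262.08,217.682,24.5737,2.67535,0.504906,0.229564,0.209198,0.433293,0.446786,0.0839977,0.172658,0.0344623,0.0666752,0.126718,0.247802,0.0452813,0.0994837,1,1
P0005,LE,FALSE,17.2446,56.4732,1,-1.72051,0.14668,0.929739,23.694,1,201.076,162.54,239.562,221.926,159.359,259.099,198.735,162.385,239.497,264.845,244.284,209.667,226.298,23.471,2.22896,0.814706,0.27517200000000003,0.278997,0.380491,0.397948,0.0799296,0.119098,0.0269365,0.053578,0.0832593,0.117747,0.0184723,0.0662705,0,1
P0006,LPI,FALSE,22.1371,35.2934,0,3.59058,0.614269,1.19938,29.1367,0,239.287,237.827,212.914,277.505,238.255,267.342,240.434,264.054,243.926,215.32,287.885,239.863,252.318,23.0573,2.47968,1.1262,0.426945,0.445598,0.438627,0.417462,0.0432668,0.0605808,0.0235439,0.036405,0.0795741,0.0743735,0.0101777,0.0497244,0,1
P0007,LE,FALSE,21.0098,55.6886,1,2.47426,0.541552,1.08672,27.3019,1,149.075,129.143,267.937,192.408,158.89,137.478,182.85,173.556,154.131,204.648,167.781,214.207,127.062,24.2757,2.18913,0.857412,0.354509,0.299388,0.306919,0.37829,0.0534217,0.101918,0.0238639,0.0360733,0.0630416,0.0900241,0.017761,0.0605747,0,1
P0008,LPI,FALSE,20.2042,52.4251,1,1.70047,0.0854746,0.734578,24.538,1,232.249,307.003,290.556,239.345,248.894,318.615,307.646,260.384,284.033,293.674,244.358,244.499,278.481,23.3711,2.08984,0.786119,0.37061500000000003,0.281923,0.417474,0.366769,0.0793993,0.166904,0.0222382,0.0408244,0.0762123,0.20202,0.0215166,0.0545163,0,1
P0009,LE,TRUE,21.0725,65.4079,1,0.233982,0.301492,1.03079,26.3232,0,272.185,231.964,255.304,309.032,229.347,226.097,348.393,286.976,301.019,275.835,267.154,241.827,320.555,23.3663,2.2525,0.792696,0.397702,0.371395,0.442369,0.470714,0.0660676,0.160466,0.0250924,0.0643787,0.0919911,0.183718,0.0347365,0.0677789,1,1
P0010,LPI,FALSE,20.4341,58.6817,0,2.79022,0.456675,0.828133,27.2859,1,220.754,261.329,283.856,341.478,269.153,218.881,218.285,292.633,269.626,200.92,268.074,247,255.601,22.1388,2.20174,1.11619,0.519893,0.451267,0.489453,0.413696,0.0438901,0.0662781,0.0164403,0.0362885,0.0575508,0.119988,0.0238672,0.0538835,0,1
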