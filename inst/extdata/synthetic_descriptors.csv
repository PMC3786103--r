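compound,pIC50,D001,D002,D003,D004,D005,D006,D007,D008
C001,2.83372,1.26808,0.00936,0.67254,1.11056,1.4709,0.46992,0.70603,1.45129
C002,3.09071,0.23904,-1.27294,1.33837,-0.13629,0.04004,0.74991,-0.10393,0.7522
C003,9.79484,-0.50302,0.2855,-1.16757,0.88015,-1.395,0.0737,1.02294,-0.2141
C004,0.27039,-0.72099,-1.2739,-1.32858,-1.67152,0.85547,-1.07254,-0.56301,0.79962
C005,3.45529,0.8149,0.58702,0.92636,0.63463,0.51735,-1.13404,-1.36635,-1.16663
C006,3.73499,-0.9347,-0.27794,0.09162,0.18428,-0.84376,-0.10954,-1.30326,-0.5488
C007,4.16673,-1.59174,0.33893,-0.26161,-0.84374,0.50613,-0.60272,-0.40561,-0.37958
C008,5.52526,0.36224,-0.71834,-0.2642,1.34648,-1.09314,-0.02195,-0.25535,-0.11193
C009,6.06801,-0.56744,-0.49932,0.28347,-1.72692,-0.89249,-0.43027,-0.35651,0.01611
C010,8.65293,0.57183,0.1831,0.6677,-0.54328,-0.91036,1.17141,1.41514,0.1202
C011,7.77798,0.21947,0.78099,0.12116,1.09424,-0.66605,0.72453,0.62392,1.74272
C012,5.03319,-0.05342,0.44004,-0.49528,0.8075,0.7048,1.64992,1.07215,1.71256
C013,8.17182,-0.15407,0.15287,-2.227,-0.32722,-0.50287,-0.71662,1.10882,0.63237
C014,5.06395,0.88909,-0.15101,0.88685,2.04792,-0.45729,-1.11299,-0.15321,0.93343
C015,1.09042,0.56968,-2.26209,-0.58852,0.09882,-0.72913,-1.93482,-1.59917,0.20932
C016,2.94446,-1.93875,-1.25729,-2.2387,0.25169,-0.26093,-0.39618,-0.11896,0.5027
C017,4.67348,-0.53688,0.5946,2.18194,0.77023,0.99915,1.74581,-0.03461,0.20422
C018,9.52997,1.26612,2.07541,1.30704,-0.12766,-0.21456,1.49838,0.66098,2.21349
C019,-0.24192,-1.42448,-1.20499,-2.43938,-0.42488,0.29939,-0.85919,-2.60008,-0.56296
C020,6.90198,-0.59314,-0.01803,-0.91846,-0.29473,-1.5621,-0.59383,-1.17678,-1.53311
C021,4.35965,-0.33186,-0.6613,0.0137,-0.32824,0.10369,-0.33571,0.30039,-0.17565
C022,12.48081,1.40714,0.41792,2.20562,2.47673,-1.6101,0.96887,1.79688,1.83715
C023,1.67248,-1.10816,-2.00486,-0.36121,0.36761,-0.28751,-1.59755,-0.7629,0.6458
C024,3.70335,2.20027,1.39236,0.40083,1.68582,1.38956,1.14543,-0.28295,0.97323
C025,2.81363,1.17335,0.46157,0.24056,0.08309,0.73436,0.60735,-1.73634,0.08896
C026,5.3223,0.82438,-0.42258,1.66082,-0.45444,-0.0491,-0.41603,0.16309,-0.9405
C027,6.4651,1.32967,0.54004,0.02349,-0.34241,-0.272,-0.5129,0.48763,0.69411
C028,3.67354,0.4197,1.54328,0.44011,-0.84046,1.86093,0.51006,0.14869,0.30306
C029,8.36829,0.7866,2.47515,1.31331,-0.2497,-0.09105,-0.77651,-0.4672,0.08253
C030,10.1545,-0.88445,0.50611,0.87501,1.09591,-1.5355,1.93648,0.35999,-0.32287
C031,10.79772,-0.00252,1.65201,0.96986,0.16953,-0.55914,1.89915,2.111,1.73834
C032,4.37862,1.35924,0.90598,1.52013,2.06282,0.93232,0.47642,-0.45468,0.98799
C033,3.367,-0.54838,0.03243,-0.87713,0.02642,0.95238,0.12929,0.07076,-0.95358
C034,2.09309,-2.58873,-1.76681,-0.3783,-0.31538,0.17643,-0.62985,-0.05748,-1.37599
C035,1.24325,0.56012,0.92428,0.40435,1.16604,2.30254,1.64521,-0.20786,0.81249
C036,4.11502,1.17357,0.61972,1.33338,1.24525,0.83464,1.065,-0.50217,-0.5618
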