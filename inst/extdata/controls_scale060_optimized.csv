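# t_f=1.0326728458519934 node_dt=0.10000000000000001 t_max=1.6000000000000001
"time","ILPSO","GMAX","RF","HAMS","VAS","GAS","SOL","TA"
0,0.05,0.05,0.05,0.05,0.05,0.05,0.05,0.05
0.1,0.20120591364995,0.000299897976734485,0.230648919127605,0.0258163774921429,0.0977681570008954,0.0148925265715336,0,0.258721341812705
0.2,0.283918115304914,0,0.297186833216614,0.112244284911799,0.240707792892561,0.0175024706718481,0.0678066905331471,0.309181068547615
0.3,0.141375290657877,0.0996823240891232,0.290456854883421,0.2736582250605,0.388842382848928,0.0815951888111447,0,0.43619151739744
0.4,0.082378154733558,0.371952791751637,0.345247922068496,0.758042522683355,0.712494383195363,0.0200185857297914,0,0.54473679160251
0.5,0.030576227345539,0.525845980636361,0.339495635496517,0.802054434098055,0.716112758955543,0.0875384360384869,0,0.632978534269267
0.6,0.00130721474212343,0.735278767551243,0.242182724786752,0.884939246551643,0.723238726532904,0.0558916519003111,0,0.606208143566408
0.7,0.0296512251713519,0.739046227134718,0.101998713803352,0.809749207719225,0.714193110195368,0.0658697018991886,0.00115845542665057,0.468185930252605
0.8,0.0262879664155706,0.623242881065059,0.112987219157231,0.741878429752249,0.566347151091646,0.0914988250832539,0,0.570245395793796
0.9,0.0289530180904684,0.601476487366029,0.175659264011245,0.655084979564706,0.492124952472738,0.123538752233096,0,0.599555895926809
1,0.0710356302520388,0.595167034219791,0.200227048519031,0.579866468138807,0.434963872354702,0.00364406792536663,0.159771082701015,0.608407026641632
1.1,0.00681825999950071,0.935462842452646,0.080949982064619,0.401898280638901,0.881628344662444,0,0.557629082064699,0.652442875525652
1.2,0.0726614375042462,0.167117535368591,0.430649934117039,0.425315666958597,0.189806540875254,0.229364451240731,0.375336450421878,0.611688914761821
1.3,0.690715583223027,0.988274967679906,0.409738316961962,0.568948925033119,0.334152965100899,0.676472188327783,0.811698952153659,0.0436170033327893
1.4,0.995679993402997,0.432024056152381,0.662716351304214,0.831337733623647,0.962168637384987,0.288659672230852,0.919430976669719,0.618465098701392
1.5,0.4362233024849,0.39923283906412,0.784607063217076,0.198471422770377,0.0225644448976278,0.76697849125758,0.961691386770653,0.756524558748211
1.6,0.693983890441867,0.374582720231999,0.397006483761964,0.475850020920756,0.849812467907951,0.681526401229975,0.960398035513446,0.924693895569275
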