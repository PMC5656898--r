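symbol,z,shell,n_electrons,zeta,coef
H,1,1s,1,2,0.31830988618379069
He,2,1s,2,3.3999999999999999,3.1277129416419269
Li,3,1s,2,5.4000000000000004,12.530586979511106
Li,3,2s2p,1,1.3,0.08741585249322352
Be,4,1s,2,7.4000000000000004,32.246701329735103
Be,4,2s2p,2,1.9500000000000002,0.59005700432925889
B,5,1s,2,9.4000000000000004,66.0957746265194
B,5,2s2p,3,2.6000000000000001,2.0979804598373644
C,6,1s,2,11.4,117.89752550406951
C,6,2s2p,4,3.25,5.4634907808264694
N,7,1s,2,13.4,191.47167259659091
N,7,2s2p,5,3.9000000000000004,11.801140086585178
O,8,1s,2,15.4,290.63793453828902
O,8,2s2p,6,4.5499999999999998,22.487728053881746
F,9,1s,2,17.399999999999999,419.21602996336929
F,9,2s2p,7,5.2000000000000002,39.16230191696414
Ne,10,1s,2,19.399999999999999,581.02567750603748
Ne,10,2s2p,8,5.8500000000000005,63.726156467559967
Na,11,1s,2,21.399999999999999,779.88659580049875
Na,11,2s2p,8,6.8500000000000005,102.31088509604361
Na,11,3s3p,1,1.4666666666666661,0.12553198770685184
Mg,12,1s,2,23.399999999999999,1019.6185034809588
Mg,12,2s2p,8,7.8500000000000005,153.97815004668107
Mg,12,3s3p,2,1.8999999999999997,0.54582187733365484
Al,13,1s,2,25.399999999999999,1304.0411191816233
Al,13,2s2p,8,8.8500000000000014,220.63781063657513
Al,13,3s3p,3,2.3333333333333335,1.5163929300144474
Si,14,1s,2,27.399999999999999,1636.9741615366972
Si,14,2s2p,8,9.8500000000000014,304.19972618282844
Si,14,3s3p,4,2.7666666666666657,3.3704713868772394
P,15,1s,2,29.399999999999999,2022.2373491803864
P,15,2s2p,8,10.850000000000001,406.57375600254375
P,15,3s3p,5,3.1999999999999993,6.5189864690440285
S,16,1s,2,31.399999999999999,2463.6504007468961
S,16,2s2p,8,11.850000000000001,529.66975941282385
S,16,3s3p,6,3.6333333333333329,11.450570377630779
Cl,17,1s,2,33.399999999999999,2965.0330348704324
Cl,17,2s2p,8,12.850000000000001,675.3975957307714
Cl,17,3s3p,7,4.0666666666666664,18.73155829374744
Ar,18,1s,2,35.399999999999999,3530.2049701851997
Ar,18,2s2p,8,13.850000000000001,845.66712427348943
Ar,18,3s3p,8,4.5,29.005988378497925
K,19,1s,2,37.399999999999999,4162.9859253254044
K,19,2s2p,8,14.850000000000001,1042.3882043580802
K,19,3s3p,8,5.166666666666667,43.901712126394955
K,19,4s4p,1,1.1891891891891888,0.066913384559354833
Ca,20,1s,2,39.399999999999999,4867.1956189252523
Ca,20,2s2p,8,15.850000000000001,1267.4706953016471
Ca,20,3s3p,8,5.833333333333333,63.183038750601966
Ca,20,4s4p,2,1.5405405405405392,0.29094408402283478
Sc,21,1s,2,41.399999999999999,5646.6537696189471
Sc,21,2s2p,8,16.850000000000001,1522.8244564212921
Sc,21,3s3p,8,6.2666666666666666,78.335732890689656
Sc,21,3d,1,2,0.31830988618379069
Sc,21,4s4p,2,1.3513513513513493,0.19637896952289921
Ti,22,1s,2,43.399999999999999,6505.1800960406963
Ti,22,2s2p,8,17.850000000000001,1810.3593470341186
Ti,22,3s3p,8,6.7000000000000002,95.735836298295453
Ti,22,3d,2,2.4333333333333322,1.1465551573477735
Ti,22,4s4p,2,1.1621621621621614,0.12490802183885751
V,23,1s,2,45.399999999999999,7446.5943168247049
V,23,2s2p,8,18.850000000000001,2131.9852264572287
V,23,3s3p,8,7.1333333333333329,115.53875493340723
V,23,3d,3,2.8666666666666671,2.8119849023127399
V,23,4s4p,2,0.97297297297297136,0.073298057616483045
Cr,24,1s,2,47.399999999999999,8474.716150605178
Cr,24,2s2p,8,19.850000000000001,2489.6119540077261
Cr,24,3s3p,8,7.333333333333333,125.53198770685195
Cr,24,3d,5,3.0666666666666678,5.7375946447380528
Cr,24,4s4p,1,0.27027027027027023,0.00078551587809160006
Mn,25,1s,2,49.399999999999999,9593.3653160163212
Mn,25,2s2p,8,20.850000000000001,2885.1493890027127
Mn,25,3s3p,8,8,162.97466172610083
Mn,25,3d,5,3.7333333333333343,10.351909068898635
Mn,25,4s4p,2,0.59459459459459341,0.016728346139838621
Fe,26,1s,2,51.399999999999999,10806.361531692339
Fe,26,2s2p,8,21.850000000000001,3320.5073907592914
Fe,26,3s3p,8,8.4333333333333336,190.91846180365849
Fe,26,3d,6,4.166666666666667,17.269416568131007
Fe,26,4s4p,2,0.40540540540540537,0.0053022321771183014
Co,27,1s,2,53.399999999999999,12117.524516267438
Co,27,2s2p,8,22.850000000000001,3797.5958185945651
Co,27,3s3p,8,8.8666666666666671,221.88670094867405
Co,27,3d,7,4.5999999999999988,27.110134696387249
Co,27,4s4p,2,0.27027027027027023,0.0015710317561832001
Ni,28,1s,2,55.399999999999999,13530.673988375824
Ni,28,2s2p,8,23.850000000000001,4318.3245318256359
Ni,28,3s3p,8,9.2999999999999989,256.03478512113526
Ni,28,3d,8,5.0333333333333341,40.589827442458109
Ni,28,4s4p,2,0.27027027027027023,0.0015710317561832001
Cu,29,1s,2,57.399999999999999,15049.629666651703
Cu,29,2s2p,8,24.850000000000001,4884.6033897696088
Cu,29,3s3p,8,9.5,272.91093866682752
Cu,29,3d,10,5.2333333333333343,57.028944461733751
Cu,29,4s4p,1,0.27027027027027023,0.00078551587809160006
Zn,30,1s,2,59.399999999999999,16678.211269729276
Zn,30,2s2p,8,25.850000000000001,5498.3422517435838
Zn,30,3s3p,8,10.166666666666666,334.49211238834715
Zn,30,3d,10,5.9000000000000012,81.717707643175984
Zn,30,4s4p,2,0.27027027027027023,0.0015710317561832001
Ga,31,1s,2,61.399999999999999,18420.238516242756
Ga,31,2s2p,8,26.850000000000001,6161.4509770646646
Ga,31,3s3p,8,12,550.03948332559025
Ga,31,3d,5,7.7333333333333343,92.009005204580419
Ga,31,4s4p,8,2.7027027027027026,6.2841270247328032
Ge,32,1s,2,63.399999999999999,20279.531124826346
Ge,32,2s2p,8,27.850000000000001,6875.8394250499541
Ge,32,3s3p,8,12.433333333333332,611.80476984312941
Ge,32,3d,6,8.1666666666666661,130.03069374873883
Ge,32,4s4p,8,2.5135135135135127,5.0546815612329983
As,33,1s,2,65.400000000000006,22259.908814114253
As,33,2s2p,8,28.850000000000001,7643.4174550165553
As,33,3s3p,8,12.866666666666667,678.02901198186191
As,33,3d,7,8.5999999999999996,177.15504884570251
As,33,4s4p,8,2.3243243243243246,3.9970566988434495
Se,34,1s,2,67.400000000000006,24365.191302740674
Se,34,2s2p,8,29.850000000000001,8466.0949262815702
Se,34,3s3p,8,13.299999999999999,748.86761570177453
Se,34,3d,8,9.0333333333333332,234.63577819191266
Se,34,4s4p,8,2.1351351351351346,3.0983197041472343
Br,35,1s,2,69.400000000000006,26599.198309339819
Br,35,2s2p,8,30.850000000000001,9345.7816981621036
Br,35,3s3p,8,13.733333333333334,824.47598696285661
Br,35,3d,9,9.4666666666666668,303.80429246380459
Br,35,4s4p,8,1.9459459459459467,2.3455378437274721
Kr,36,1s,2,71.400000000000006,28965.749552545898
Kr,36,2s2p,8,31.850000000000001,10284.387629975256
Kr,36,3s3p,8,14.166666666666666,905.00953172509458
Kr,36,3d,10,9.9000000000000004,386.06970531780746
Kr,36,4s4p,8,1.7567567567567566,1.7257783841672454
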