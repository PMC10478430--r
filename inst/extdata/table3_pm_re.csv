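pair_id,mirna_id,pm_re
P1,miRNA20a,0.03585778
P1,miRNA21,0.380851302
P1,miRNA29a,1.06875214
P1,miRNA31,0.016550802
P1,miRNA92,1.376933695
P1,miRNA224,0.348727511
P2,miRNA20a,1.09645
P2,miRNA21,0.744853227
P2,miRNA29a,0.634025639
P2,miRNA31,0.28162107
P2,miRNA92,43.60894807
P2,miRNA224,19.04037414
P3,miRNA20a,1.692489273
P3,miRNA21,0.19090725
P3,miRNA29a,0.29605899
P3,miRNA31,0.066645422
P3,miRNA92,16.1857784
P3,miRNA224,0.117350079
P4,miRNA20a,1.827198884
P4,miRNA21,0.415489365
P4,miRNA29a,0.385843106
P4,miRNA31,0.125200289
P4,miRNA92,0.089000864
P4,miRNA224,0.038028682
P5,miRNA20a,0.165149779
P5,miRNA21,0.405168741
P5,miRNA29a,1.017076664
P5,miRNA31,0.339575209
P5,miRNA92,0.423256334
P5,miRNA224,0.035356511
P6,miRNA20a,9.032603896
P6,miRNA21,1.486654886
P6,miRNA29a,2.40478338
P6,miRNA31,0.446682873
P6,miRNA92,1.377598043
P6,miRNA224,0.346092903
P7,miRNA20a,0.086177313
P7,miRNA21,5.109981798
P7,miRNA29a,2.836372188
P7,miRNA31,0.223606276
P7,miRNA92,0.545315661
P7,miRNA224,0.025755563
P8,miRNA20a,0.036665352
P8,miRNA21,0.595136416
P8,miRNA29a,0.609622383
P8,miRNA31,0.672004739
P8,miRNA92,15.27884066
P8,miRNA224,0.050267673
P9,miRNA20a,0.791830378
P9,miRNA21,0.433974719
P9,miRNA29a,7.749368098
P9,miRNA31,1.218222488
P9,miRNA92,39.81362463
P9,miRNA224,2.231345879
P10,miRNA20a,1.394741901
P10,miRNA21,0.453943997
P10,miRNA29a,0.435070972
P10,miRNA31,0.40896525
P10,miRNA92,0.073191164
P10,miRNA224,0.06857601
P11,miRNA20a,1.114735233
P11,miRNA21,1.975651409
P11,miRNA29a,1.682212004
P11,miRNA31,42.32879328
P11,miRNA92,153.2597858
P11,miRNA224,0.831435329
P12,miRNA20a,14.54973359
P12,miRNA21,3.999988297
P12,miRNA29a,32.62794428
P12,miRNA31,0.375873656
P12,miRNA92,18.4565922
P12,miRNA224,1.431082595
P13,miRNA20a,14.40626287
P13,miRNA21,0.631038396
P13,miRNA29a,1.104248944
P13,miRNA31,0.291989528
P13,miRNA92,18.90293824
P13,miRNA224,1.304937537
P14,miRNA20a,0.928942468
P14,miRNA21,1.719170222
P14,miRNA29a,1.31107852
P14,miRNA31,6.881585216
P14,miRNA92,1.284949901
P14,miRNA224,0.353125807
P15,miRNA20a,20.67402285
P15,miRNA21,1.515992607
P15,miRNA29a,1.799639358
P15,miRNA31,1.184994819
P15,miRNA92,1.523399321
P15,miRNA224,0.250151106
P16,miRNA20a,1.228038849
P16,miRNA21,0.905169764
P16,miRNA29a,3.674614842
P16,miRNA31,0.411291757
P16,miRNA92,34.59836117
P16,miRNA224,0.896321213
P17,miRNA20a,26.635528
P17,miRNA21,0.026303388
P17,miRNA29a,0.052693645
P17,miRNA31,0.041371318
P17,miRNA92,0.138602656
P17,miRNA224,0.035727369
P18,miRNA20a,0.67089814
P18,miRNA21,2.075354337
P18,miRNA29a,18.2393941
P18,miRNA31,5.40911457
P18,miRNA92,17.46464893
P18,miRNA224,1.408999347
P19,miRNA20a,0.114868611
P19,miRNA21,11.72405865
P19,miRNA29a,212.6193329
P19,miRNA31,0.330265922
P19,miRNA92,4589.949761
P19,miRNA224,15.08672611
P20,miRNA20a,11.96089471
P20,miRNA21,1.273562362
P20,miRNA29a,10.3128689
P20,miRNA31,0.562961827
P20,miRNA92,25.40671426
P20,miRNA224,1.975487901
P22,miRNA20a,10.67585162
P22,miRNA21,3.782676577
P22,miRNA29a,20.47102061
P22,miRNA31,0.034650289
P22,miRNA92,87.78290945
P22,miRNA224,3.899262033
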