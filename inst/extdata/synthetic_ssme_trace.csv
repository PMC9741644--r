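"time_s","current_nA"
0,0.0524586422546371
0.01,0.021428075882999
0.02,0.0529014389318318
0.03,0.0542550552263743
0.04,0.0483478370655354
0.05,0.0569850701650158
0.06,0.0499653979862029
0.07,0.0352559773374267
0.08,0.0489832035418112
0.09,0.0565974572813412
0.1,0.0700706434702424
0.11,0.059053932718311
0.12,0.0487128176006957
0.13,0.0449936625383801
0.14,0.0415870062835303
0.15,0.0539087324458102
0.16,0.0492219826492351
0.17,0.0551133689710342
0.18,0.0472036239713269
0.19,0.0545504083055443
0.2,0.0409593791374408
0.21,0.0535433418720695
0.22,0.0587369708809047
0.23,0.0492090329821763
0.24,0.032976484103952
0.25,0.0544681526596314
0.26,0.0339432062222229
0.27,0.059063924267766
0.28,0.0558732312263359
0.29,0.0393908712412041
0.3,0.0466603930136428
0.31,0.0628585420408134
0.32,0.0480946314525937
0.33,0.0526998643895348
0.34,0.0489445577007754
0.35,0.0507823098133254
0.36,0.0503761106510395
0.37,0.0504747339662775
0.38,0.0450605603633081
0.39,0.0514454218288311
0.4,0.0454362678821369
0.41,0.0570772271216556
0.42,0.043013964929126
0.43,0.0402727225706405
0.44,0.0514793734265948
0.45,0.037639791802382
0.46,0.0428109203393873
0.47,0.0566234927281145
0.48,0.0508710866571117
0.49,0.0677931024514833
0.5,2.24958779211909
0.51,2.14489210542147
0.52,2.02123863150141
0.53,1.95309684735128
0.54,1.84513287096973
0.55,1.75505423306273
0.56,1.69186722814893
0.57,1.58906562099139
0.58,1.5299328830496
0.59,1.46196829051172
0.6,1.39311049365051
0.61,1.31623008794576
0.62,1.25419440336717
0.63,1.19793685562897
0.64,1.11683035635861
0.65,1.09502026857708
0.66,1.03699167039847
0.67,0.97296660653631
0.68,0.934002507757298
0.69,0.89340569583963
0.7,0.855989722316661
0.71,0.82258141485199
0.72,0.775953570006828
0.73,0.727441209330643
0.74,0.709182338217337
0.75,0.676284599992213
0.76,0.635996349484509
0.77,0.614122096940456
0.78,0.600228273804105
0.79,0.549568917322707
0.8,0.552600916120472
0.81,0.52066063182704
0.82,0.495200217175356
0.83,0.459936004189787
0.84,0.452498302369746
0.85,0.426780569666436
0.86,0.422333038387843
0.87,0.407794242292195
0.88,0.360580368878621
0.89,0.375742196689594
0.9,0.334846500421503
0.91,0.317676568443768
0.92,0.320597104075359
0.93,0.301297800980423
0.94,0.284814445414242
0.95,0.27765907270232
0.96,0.274108814987025
0.97,0.254031509213379
0.98,0.255341113382706
0.99,0.232745473616321
1,0.234093640301304
1.01,0.214926142069545
1.02,0.205165053193442
1.03,0.217020655147713
1.04,0.19128293594759
1.05,0.208611366846862
1.06,0.180861142345585
1.07,0.179628756993919
1.08,0.156398451819064
1.09,0.17723723489883
1.1,0.163962338487087
1.11,0.151451448465786
1.12,0.16312278272
1.13,0.150881846187907
1.14,0.152081465415041
1.15,0.142182424294612
1.16,0.12674501555525
1.17,0.140226605129573
1.18,0.127360602966148
1.19,0.123536729791168
1.2,0.102340983304515
1.21,0.10498457865303
1.22,0.0936142052870788
1.23,0.100328096871026
1.24,0.127488855680522
1.25,0.0917036902180859
1.26,0.127230276127298
1.27,0.102949351012641
1.28,0.0915366588964462
1.29,0.0915479061171359
1.3,0.0949487978429799
1.31,0.0822002388711772
1.32,0.0828548251403416
1.33,0.070662497169294
1.34,0.0939282602754659
1.35,0.0761039063376389
1.36,0.0796515681738038
1.37,0.080417403224853
1.38,0.0710363569773851
1.39,0.0766403394401773
1.4,0.0892582852107707
1.41,0.0840023099775256
1.42,0.0865838258664128
1.43,0.0497605884676578
1.44,0.0874067591270742
1.45,0.0669927669913828
1.46,0.0756448345872127
1.47,0.0696386527272106
1.48,0.0764934105791601
1.49,0.0688356279829352
1.5,0.0558490771128777
1.51,0.0452162004663698
1.52,0.0573237692110683
1.53,0.0530779394628704
1.54,0.0395854381617362
1.55,0.0479444618037681
1.56,0.0592971803896342
1.57,0.0571284906242824
1.58,0.0578955497894578
1.59,0.0469808660187324
1.6,0.0437111897570366
1.61,0.0399551120630262
1.62,0.0497382519508654
1.63,0.0324033566176395
1.64,0.0420272879118604
1.65,0.0557955913672949
1.66,0.0433661424780372
1.67,0.0404052743127538
1.68,0.045022582731601
1.69,0.0687445552441261
1.7,0.0524355428031766
1.71,0.0339653559241513
1.72,0.0635970450987912
1.73,0.0490720239084257
1.74,0.0501913031248381
1.75,0.0529267430335566
1.76,0.0544564414683989
1.77,0.0351810091847682
1.78,0.0372424195044011
1.79,0.0619670534703866
1.8,0.0855181652893118
1.81,0.0564443083965589
1.82,0.0428087690763116
1.83,0.0620976696139957
1.84,0.0411717808810104
1.85,0.0463975837624235
1.86,0.0360297711026571
1.87,0.044756118862034
1.88,0.0661357298417541
1.89,0.0548506138625342
1.9,0.0638049441848247
1.91,0.0507057862041788
1.92,0.0280715661271025
1.93,0.0435317358803199
1.94,0.0451624364036113
1.95,0.0495249894177656
1.96,0.0710285895749563
1.97,0.0424042334497995
1.98,0.0621504875617719
1.99,0.0315220279744049
2,0.0531537366596765
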