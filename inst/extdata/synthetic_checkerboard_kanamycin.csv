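"harmane_uM","0","0.625","1.25","2.5","5","10","20","40","80"
0,0.620610130145973,0.592847613331624,0.601526868533916,0.601682523541873,0.61307037282739,0.59531543168278,0.297447773830298,0.000148808142518445,3.58863582969001e-08
9,0.608984884562524,0.601215888699762,0.615474507320576,0.605231735343902,0.601536297064757,0.588559710356117,0.012509978892785,3.42872244648497e-06,8.74760896371635e-10
18,0.603596833378762,0.598959137048249,0.603824291796555,0.592457417627849,0.616626317063384,0.478512839944245,0.00071120670041759,1.91231331784907e-07,5.07152266810601e-11
36,0.589594641237345,0.595098490433278,0.589153102327244,0.60340876671869,0.588372116579587,0.0268067718401421,9.91023036174153e-06,2.79205926830458e-09,7.31691713377812e-13
72,0.60269843896828,0.598581461471597,0.601776687380674,0.591535180375666,0.128559633708431,8.95528005761036e-05,3.4438436672969e-08,1.040645569941e-11,2.72314947918789e-15
144,0.613003393448636,0.605512924183524,0.596299452285105,0.110008119505538,0.000174437267934441,1.06618119200039e-07,3.95444377026254e-11,1.2385815974532e-14,3.50334212231534e-18
287.5,0.586421501688982,0.359095762026416,0.0150262781772069,6.42404498071227e-05,9.40548938155073e-08,5.93113204082700e-11,2.47759408793474e-14,7.82258835847151e-18,2.16340742415039e-21
575,0.0952677129628365,0.000278868612898434,4.84089518001599e-06,2.29156416724522e-08,3.41639192493114e-11,2.22007541339945e-14,9.37614549803333e-18,3.0191114748251e-21,8.59455472500886e-25
1150,2.79464472784128e-05,7.11524690036221e-08,1.38783198427684e-09,6.91424532254301e-12,1.01700461159069e-14,6.8417762364389e-18,2.90040599641004e-21,9.50586182102415e-25,2.69627423404456e-28
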