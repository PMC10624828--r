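ac,fl,bpd,efw_g
15.0,3.0,4.0,302.55198038723066
15.0,3.0,6.0,349.94516702835727
15.0,3.0,8.0,404.76224868787346
15.0,3.0,10.0,468.16613972436431
15.0,4.25,4.0,416.79739889405443
15.0,4.25,6.0,482.08653331664213
15.0,4.25,8.0,557.60286945632656
15.0,4.25,10.0,644.94844501642885
15.0,5.5,4.0,574.18256361273336
15.0,5.5,6.0,664.12526161970146
15.0,5.5,8.0,768.15701324381996
15.0,5.5,10.0,888.48479510715504
15.0,6.75,4.0,790.99729804382308
15.0,6.75,6.0,914.90289116153368
15.0,6.75,8.0,1058.2176479310284
15.0,6.75,10.0,1223.9819124092851
15.0,8.0,4.0,1089.6825594561704
15.0,8.0,6.0,1260.375637894425
15.0,8.0,8.0,1457.8068950562789
15.0,8.0,10.0,1686.1647269094908
21.25,3.0,4.0,504.28378052297282
21.25,3.0,6.0,583.27719943839193
21.25,3.0,8.0,674.64452462038911
21.25,3.0,10.0,780.32406382163936
21.25,4.25,4.0,653.48782388809865
21.25,4.25,6.0,755.8532764810491
21.25,4.25,8.0,874.25374227778639
21.25,4.25,10.0,1011.2010223003608
21.25,5.5,4.0,846.83734132224067
21.25,5.5,6.0,979.48998540869887
21.25,5.5,8.0,1132.9219729705561
21.25,5.5,10.0,1310.3882795738266
21.25,6.75,4.0,1097.393794410653
21.25,6.75,6.0,1269.2947975068908
21.25,6.75,8.0,1468.1231944119866
21.25,6.75,10.0,1698.0970206479986
21.25,8.0,4.0,1422.083180851088
21.25,8.0,6.0,1644.8450795602698
21.25,8.0,8.0,1902.5014655854618
21.25,8.0,10.0,2200.5183780119064
27.5,3.0,4.0,840.52377040489122
27.5,3.0,6.0,972.18742660082244
27.5,3.0,8.0,1124.4755064873885
27.5,3.0,10.0,1300.6187182559055
27.5,4.25,4.0,1024.5897337726749
27.5,4.25,6.0,1185.0863612319347
27.5,4.25,8.0,1370.7239466538979
27.5,4.25,10.0,1585.4406897209403
27.5,5.5,4.0,1248.9642286340888
27.5,5.5,6.0,1444.6079481694455
27.5,5.5,8.0,1670.8982339683451
27.5,5.5,10.0,1932.6357104820927
27.5,6.75,4.0,1522.4744041341732
27.5,6.75,6.0,1760.9620633427467
27.5,6.75,8.0,2036.8075680693408
27.5,6.75,10.0,2355.8628295884406
27.5,8.0,4.0,1855.8804632688909
27.5,8.0,6.0,2146.5944393160802
27.5,8.0,8.0,2482.8472404879785
27.5,8.0,10.0,2871.7722857620144
33.75,3.0,4.0,1400.957627237171
33.75,3.0,6.0,1620.4103183713765
33.75,3.0,8.0,1874.2391267483428
33.75,3.0,10.0,2167.8288914902539
33.75,4.25,4.0,1606.432567184485
33.75,4.25,6.0,1858.0718338834371
33.75,4.25,8.0,2149.1290766856552
33.75,4.25,10.0,2485.7789155559023
33.75,5.5,4.0,1842.0440010025053
33.75,5.5,6.0,2130.5905675427252
33.75,5.5,8.0,2464.3364458349103
33.75,5.5,10.0,2850.3618718608897
33.75,6.75,4.0,2112.2119726296899
33.75,6.75,6.0,2443.0789400722406
33.75,6.75,8.0,2825.7744889087018
33.75,6.75,10.0,3268.4172955668483
33.75,8.0,4.0,2422.0048027583126
33.75,8.0,6.0,2801.3991981144977
33.75,8.0,8.0,3240.2237428509641
33.75,8.0,10.0,3747.7878592960165
40.0,3.0,4.0,2335.0705148630771
40.0,3.0,6.0,2700.8471083246618
40.0,3.0,8.0,3123.9206936641156
40.0,3.0,10.0,3613.2665452345182
40.0,4.25,4.0,2518.6916361232023
40.0,4.25,6.0,2913.2315186566219
40.0,4.25,8.0,3369.5740119888295
40.0,4.25,10.0,3897.4001721312484
40.0,5.5,4.0,2716.7520284709514
40.0,5.5,6.0,3142.3170364348434
40.0,5.5,8.0,3634.5445789640405
40.0,5.5,10.0,4203.8769937308344
40.0,6.75,4.0,2930.3871416199037
40.0,6.75,6.0,3389.4169736368654
40.0,6.75,8.0,3920.3514300254185
40.0,6.75,10.0,4534.4539944317163
40.0,8.0,4.0,3160.8217127583482
40.0,8.0,6.0,3655.947916131249
40.0,8.0,8.0,4228.6330518149915
40.0,8.0,10.0,4891.0263212459359
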