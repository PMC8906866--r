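"source","density_per_ha","pct_mating","pct_spawning"
"bahamas_synthetic",10,0,0.5828924710349257
"bahamas_synthetic",10,0.36728664844416448,7.8545748269076334
"bahamas_synthetic",10,0,0.0022107032632482622
"bahamas_synthetic",10,3.1905616042755831,10.368682127598714
"bahamas_synthetic",10,0.65901554363072101,8.7224655835174438
"bahamas_synthetic",25,0,0
"bahamas_synthetic",25,0.97485810485697055,9.88922581744316
"bahamas_synthetic",25,1.4766494102584347,12.571866901594444
"bahamas_synthetic",25,1.1515627033069846,7.1490292433601557
"bahamas_synthetic",25,0,1.1878923752568431
"bahamas_synthetic",50,3.0235694289329316,10.885899488432818
"bahamas_synthetic",50,0.7796935648540978,12.177444073197091
"bahamas_synthetic",50,0,0
"bahamas_synthetic",50,0,0.74003761983257632
"bahamas_synthetic",50,2.249868928317452,10.754123996505466
"bahamas_synthetic",100,10.070132781791239,9.1349599380166993
"bahamas_synthetic",100,10.127619473623808,12.635735611966345
"bahamas_synthetic",100,12.047672421192299,12.540805231389903
"bahamas_synthetic",100,11.802442390017877,11.620427299029997
"bahamas_synthetic",100,11.347802642256717,13.393666909081691
"bahamas_synthetic",150,11.997954743216436,11.336972851130609
"bahamas_synthetic",150,11.724272601462134,7.6668155830839275
"bahamas_synthetic",150,10.309129966730382,9.0734691715262272
"bahamas_synthetic",150,6.1812966082732546,7.7707747702032126
"bahamas_synthetic",150,11.399651495789421,9.2731987271213772
"bahamas_synthetic",200,10.047742520941998,8.9792666455517516
"bahamas_synthetic",200,9.8484089865893409,10.304231746288471
"bahamas_synthetic",200,7.2184952322014517,8.3981567028951094
"bahamas_synthetic",200,9.2036998897827598,10.53605754480815
"bahamas_synthetic",200,10.995883120399405,8.9108307121623653
"bahamas_synthetic",250,12.877359103058089,13.754574538745292
"bahamas_synthetic",250,9.9544245453140086,11.653414952034412
"bahamas_synthetic",250,10.935343223118739,12.040348458990454
"bahamas_synthetic",250,10.052389918834191,10.988370715652691
"bahamas_synthetic",250,7.4058808863427874,13.584352161038836
"bahamas_synthetic",500,9.3300108734006404,8.9485270921020472
"bahamas_synthetic",500,9.3714200925793012,9.2967105392788678
"bahamas_synthetic",500,10.041373206577628,13.084564477083326
"bahamas_synthetic",500,12.360050743967767,8.9186072933792673
"bahamas_synthetic",500,11.686351496915089,9.8052385127960697
"bahamas_synthetic",1000,9.8309528074928263,9.4343841411160323
"bahamas_synthetic",1000,9.6532766397269842,9.5800142629029867
"bahamas_synthetic",1000,11.553926750809476,9.6617733940468824
"bahamas_synthetic",1000,11.273326397347315,11.208376662535654
"bahamas_synthetic",1000,8.7824886109009608,9.8653390354607886
"bahamas_synthetic",2500,8.7450096860757611,9.2080850757714856
"bahamas_synthetic",2500,10.88916392427366,12.906077650340823
"bahamas_synthetic",2500,11.697065849030832,9.7908411829062629
"bahamas_synthetic",2500,9.9353075756995448,9.8608869399132271
"bahamas_synthetic",2500,11.92221545290843,10.019618517572876
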