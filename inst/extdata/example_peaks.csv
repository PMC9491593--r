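frequency_hz,pulse_index,amplitude
10,1,0.38734862185453334
10,2,0.31270438920101479
10,3,0.29401585340787645
10,4,0.27910271087056715
10,5,0.2656291562504251
10,6,0.25224615758663421
10,7,0.2797470027725743
10,8,0.24981280079687115
10,9,0.2877245392090495
10,10,0.24981216994793784
10,11,0.2745007841084055
10,12,0.29224280854298568
10,13,0.22559552905519506
10,14,0.24569965308516789
10,15,0.24832732574908953
10,16,0.26226534312901384
10,17,0.24558380825747983
10,18,0.20258602036643078
10,19,0.20649989221056164
10,20,0.27465988643817441
10,21,0.24517470963908805
10,22,0.21844614914275567
10,23,0.24761626580226845
10,24,0.27274819174830517
10,25,0.28508256294864198
10,26,0.24292991058438618
10,27,0.24606914585146622
10,28,0.21877481669449908
10,29,0.25907140886504981
10,30,0.23913223529891758
10,31,0.25898717483654388
10,32,0.26350731747876333
10,33,0.26949339172889131
10,34,0.23969534964047687
10,35,0.25988445169143476
10,36,0.2196113577090287
10,37,0.23651382045364644
10,38,0.23530943981516014
10,39,0.20697462629240992
10,40,0.25138686219082484
10,41,0.25446586456566356
10,42,0.2441879763986351
10,43,0.2644738485806275
10,44,0.23756061494209521
10,45,0.2259320460023507
10,46,0.25857696665145108
10,47,0.23602563861370229
10,48,0.276906475300708
10,49,0.24291217750960048
10,50,0.26261575781860785
20,1,0.36833489543182152
20,2,0.29576171441152777
20,3,0.27779662611756351
20,4,0.21918166631373676
20,5,0.1863022263924079
20,6,0.17855234586490124
20,7,0.18068480057352065
20,8,0.16758926274678998
20,9,0.11052877911029774
20,10,0.16931675066484114
20,11,0.157139120261583
20,12,0.16693351528501857
20,13,0.17398124744379492
20,14,0.18871296249003355
20,15,0.15009788764262688
20,16,0.18684589121171674
20,17,0.16929518610281336
20,18,0.18201059854086851
20,19,0.17986185919937817
20,20,0.17622985017030623
20,21,0.14425065578139981
20,22,0.161517871400852
20,23,0.17445050868447973
20,24,0.14586436600647351
20,25,0.15330662918418295
20,26,0.1736748670537222
20,27,0.17706678270409323
20,28,0.17154880012182333
20,29,0.14708794805290962
20,30,0.14320885779055212
20,31,0.19056002238548053
20,32,0.16781690950085201
20,33,0.16474497603823213
20,34,0.16095068690363565
20,35,0.14149468350137878
20,36,0.17423430933019274
20,37,0.15920618554713473
20,38,0.15982936582056329
20,39,0.18005872349592308
20,40,0.17803645207607363
20,41,0.1883739190001168
20,42,0.15451115401710661
20,43,0.1749293717294706
20,44,0.18835567948346615
20,45,0.1430087529045147
20,46,0.14753993493008011
20,47,0.14262903643585009
20,48,0.1366935459089087
20,49,0.16459148316541661
20,50,0.17498112786175235
130,1,0.3842674974327227
130,2,0.34205209781163798
130,3,0.20493343635819961
130,4,0.16939864999662646
130,5,0.068706967974516475
130,6,0.054719430777297337
130,7,0.033120163402043809
130,8,0.03395444484435467
130,9,0.037899897897169368
130,10,0.035986289400162144
130,11,0.033053507896308135
130,12,0.035275919791500021
130,13,0.024385759824081501
130,14,0.023946499169068523
130,15,0.0029021207981995076
130,16,0.026020473320641963
130,17,0.023611679970929736
130,18,0.081837969078794981
130,19,0.0081479664623493805
130,20,0.035300026859257823
130,21,0.0057208348722381924
130,22,0.0061253379217220891
130,23,0.035024352799002664
130,24,0.014689543411715487
130,25,0.032712015736215835
130,26,0.024975837679607732
130,27,0.02160947820290646
130,28,-0.0039697302184786773
130,29,0.010525123428168946
130,30,0.035974231149046756
130,31,0.043006001093577571
130,32,0.023782322702800465
130,33,0.032715092994116506
130,34,0.053064869981402113
130,35,0.058808680216237613
130,36,0.012825119447953122
130,37,0.030583075475535501
130,38,0.054485980543336268
130,39,0.024194421048070614
130,40,0.031756805234305206
130,41,0.031146744939953355
130,42,0.016617948584546512
130,43,0.024646978621777241
130,44,0.032172977990175364
130,45,0.02520512064911748
130,46,0.052886472732514705
130,47,0.023988238380098684
130,48,0.024854948142645938
130,49,0.045336691297429579
130,50,0.013559313870406146
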