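sex,race,age_lo,age_hi,rate
male,white,40,44,0.002946
male,white,45,49,0.004438
male,white,50,54,0.006688
male,white,55,59,0.01008
male,white,60,64,0.01518
male,white,65,69,0.02288
male,white,70,74,0.03448
male,white,75,79,0.05195
male,white,80,84,0.07828
male,white,85,89,0.118
female,white,40,44,0.001826
female,white,45,49,0.002752
female,white,50,54,0.004146
female,white,55,59,0.006248
female,white,60,64,0.009415
female,white,65,69,0.01419
female,white,70,74,0.02138
female,white,75,79,0.03221
female,white,80,84,0.04853
female,white,85,89,0.07313
male,black,40,44,0.003976
male,black,45,49,0.005992
male,black,50,54,0.009029
male,black,55,59,0.0136
male,black,60,64,0.0205
male,black,65,69,0.03089
male,black,70,74,0.04654
male,black,75,79,0.07013
male,black,80,84,0.1057
male,black,85,89,0.1592
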