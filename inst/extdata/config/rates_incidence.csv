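sex,race,age_lo,age_hi,rate
male,white,40,44,2.076e-5
male,white,45,49,3.416e-5
male,white,50,54,5.424e-5
male,white,55,59,8.185e-5
male,white,60,64,1.156e-4
male,white,65,69,1.515e-4
male,white,70,74,1.843e-4
male,white,75,79,2.104e-4
male,white,80,84,2.29e-4
male,white,85,89,2.413e-4
female,white,40,44,3.114e-6
female,white,45,49,5.123e-6
female,white,50,54,8.136e-6
female,white,55,59,1.228e-5
female,white,60,64,1.734e-5
female,white,65,69,2.272e-5
female,white,70,74,2.764e-5
female,white,75,79,3.156e-5
female,white,80,84,3.435e-5
female,white,85,89,3.619e-5
male,black,40,44,5.19e-6
male,black,45,49,8.539e-6
male,black,50,54,1.356e-5
male,black,55,59,2.046e-5
male,black,60,64,2.89e-5
male,black,65,69,3.787e-5
male,black,70,74,4.606e-5
male,black,75,79,5.259e-5
male,black,80,84,5.725e-5
male,black,85,89,6.032e-5
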