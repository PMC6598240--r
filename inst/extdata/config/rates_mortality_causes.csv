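cause,sex,race,age_lo,age_hi,rate
heart_disease,male,white,40,44,7.66e-4
heart_disease,male,white,45,49,0.001154
heart_disease,male,white,50,54,0.001739
heart_disease,male,white,55,59,0.002621
heart_disease,male,white,60,64,0.003947
heart_disease,male,white,65,69,0.005949
heart_disease,male,white,70,74,0.008965
heart_disease,male,white,75,79,0.01351
heart_disease,male,white,80,84,0.02035
heart_disease,male,white,85,89,0.03068
heart_disease,female,white,40,44,4.748e-4
heart_disease,female,white,45,49,7.155e-4
heart_disease,female,white,50,54,0.001078
heart_disease,female,white,55,59,0.001624
heart_disease,female,white,60,64,0.002448
heart_disease,female,white,65,69,0.003689
heart_disease,female,white,70,74,0.005559
heart_disease,female,white,75,79,0.008375
heart_disease,female,white,80,84,0.01262
heart_disease,female,white,85,89,0.01901
heart_disease,male,black,40,44,0.001034
heart_disease,male,black,45,49,0.001558
heart_disease,male,black,50,54,0.002348
heart_disease,male,black,55,59,0.003536
heart_disease,male,black,60,64,0.00533
heart_disease,male,black,65,69,0.008031
heart_disease,male,black,70,74,0.0121
heart_disease,male,black,75,79,0.01823
heart_disease,male,black,80,84,0.02748
heart_disease,male,black,85,89,0.04139
stroke,male,white,40,44,1.473e-4
stroke,male,white,45,49,2.219e-4
stroke,male,white,50,54,3.344e-4
stroke,male,white,55,59,5.04e-4
stroke,male,white,60,64,7.59e-4
stroke,male,white,65,69,0.001144
stroke,male,white,70,74,0.001724
stroke,male,white,75,79,0.002598
stroke,male,white,80,84,0.003914
stroke,male,white,85,89,0.0059
stroke,female,white,40,44,9.13e-5
stroke,female,white,45,49,1.376e-4
stroke,female,white,50,54,2.073e-4
stroke,female,white,55,59,3.124e-4
stroke,female,white,60,64,4.708e-4
stroke,female,white,65,69,7.095e-4
stroke,female,white,70,74,0.001069
stroke,female,white,75,79,0.001611
stroke,female,white,80,84,0.002426
stroke,female,white,85,89,0.003656
stroke,male,black,40,44,1.988e-4
stroke,male,black,45,49,2.996e-4
stroke,male,black,50,54,4.515e-4
stroke,male,black,55,59,6.8e-4
stroke,male,black,60,64,0.001025
stroke,male,black,65,69,0.001544
stroke,male,black,70,74,0.002327
stroke,male,black,75,79,0.003506
stroke,male,black,80,84,0.005285
stroke,male,black,85,89,0.00796
lung_cancer,male,white,40,44,2.062e-4
lung_cancer,male,white,45,49,3.107e-4
lung_cancer,male,white,50,54,4.682e-4
lung_cancer,male,white,55,59,7.056e-4
lung_cancer,male,white,60,64,0.001063
lung_cancer,male,white,65,69,0.001602
lung_cancer,male,white,70,74,0.002414
lung_cancer,male,white,75,79,0.003637
lung_cancer,male,white,80,84,0.00548
lung_cancer,male,white,85,89,0.00826
lung_cancer,female,white,40,44,1.278e-4
lung_cancer,female,white,45,49,1.926e-4
lung_cancer,female,white,50,54,2.902e-4
lung_cancer,female,white,55,59,4.374e-4
lung_cancer,female,white,60,64,6.59e-4
lung_cancer,female,white,65,69,9.933e-4
lung_cancer,female,white,70,74,0.001497
lung_cancer,female,white,75,79,0.002255
lung_cancer,female,white,80,84,0.003397
lung_cancer,female,white,85,89,0.005119
lung_cancer,male,black,40,44,2.783e-4
lung_cancer,male,black,45,49,4.194e-4
lung_cancer,male,black,50,54,6.32e-4
lung_cancer,male,black,55,59,9.52e-4
lung_cancer,male,black,60,64,0.001435
lung_cancer,male,black,65,69,0.002162
lung_cancer,male,black,70,74,0.003258
lung_cancer,male,black,75,79,0.004909
lung_cancer,male,black,80,84,0.007399
lung_cancer,male,black,85,89,0.01114
colon_cancer,male,white,40,44,5.892e-5
colon_cancer,male,white,45,49,8.876e-5
colon_cancer,male,white,50,54,1.338e-4
colon_cancer,male,white,55,59,2.016e-4
colon_cancer,male,white,60,64,3.036e-4
colon_cancer,male,white,65,69,4.576e-4
colon_cancer,male,white,70,74,6.896e-4
colon_cancer,male,white,75,79,0.001039
colon_cancer,male,white,80,84,0.001566
colon_cancer,male,white,85,89,0.00236
colon_cancer,female,white,40,44,3.652e-5
colon_cancer,female,white,45,49,5.504e-5
colon_cancer,female,white,50,54,8.292e-5
colon_cancer,female,white,55,59,1.25e-4
colon_cancer,female,white,60,64,1.883e-4
colon_cancer,female,white,65,69,2.838e-4
colon_cancer,female,white,70,74,4.276e-4
colon_cancer,female,white,75,79,6.442e-4
colon_cancer,female,white,80,84,9.706e-4
colon_cancer,female,white,85,89,0.001463
colon_cancer,male,black,40,44,7.952e-5
colon_cancer,male,black,45,49,1.198e-4
colon_cancer,male,black,50,54,1.806e-4
colon_cancer,male,black,55,59,2.72e-4
colon_cancer,male,black,60,64,4.1e-4
colon_cancer,male,black,65,69,6.178e-4
colon_cancer,male,black,70,74,9.308e-4
colon_cancer,male,black,75,79,0.001403
colon_cancer,male,black,80,84,0.002114
colon_cancer,male,black,85,89,0.003184
injury,male,white,40,44,6e-4
injury,male,white,45,49,6e-4
injury,male,white,50,54,6e-4
injury,male,white,55,59,6e-4
injury,male,white,60,64,6e-4
injury,male,white,65,69,6e-4
injury,male,white,70,74,6e-4
injury,male,white,75,79,6e-4
injury,male,white,80,84,6e-4
injury,male,white,85,89,6e-4
injury,female,white,40,44,3e-4
injury,female,white,45,49,3e-4
injury,female,white,50,54,3e-4
injury,female,white,55,59,3e-4
injury,female,white,60,64,3e-4
injury,female,white,65,69,3e-4
injury,female,white,70,74,3e-4
injury,female,white,75,79,3e-4
injury,female,white,80,84,3e-4
injury,female,white,85,89,3e-4
injury,male,black,40,44,8e-4
injury,male,black,45,49,8e-4
injury,male,black,50,54,8e-4
injury,male,black,55,59,8e-4
injury,male,black,60,64,8e-4
injury,male,black,65,69,8e-4
injury,male,black,70,74,8e-4
injury,male,black,75,79,8e-4
injury,male,black,80,84,8e-4
injury,male,black,85,89,8e-4
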