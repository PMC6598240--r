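factor,level,rr,ci_low,ci_high,prevalence,is_reference
segment_length,under_3cm,1,1,1,0.45,TRUE
segment_length,3_to_6cm,2.2,1.4,3.4,0.35,FALSE
segment_length,6cm_plus,4,2.4,6.7,0.2,FALSE
dysplasia,none,1,1,1,0.8,TRUE
dysplasia,indefinite,2.5,1.2,5.2,0.08,FALSE
dysplasia,confirmed_low_grade,5,2.6,9.5,0.09,FALSE
dysplasia,high_grade,10,5,20,0.03,FALSE
sgerd,rarely_or_never,1,1,1,0.5,TRUE
sgerd,less_than_weekly,1.2649,1.0954,1.4491,0.2,FALSE
sgerd,weekly_to_daily,2.1213,1.8708,2.4083,0.2,FALSE
sgerd,more_than_daily,2.5495,2.1909,2.9665,0.1,FALSE
smoking,never,1,1,1,0.4,TRUE
smoking,ever,1.5,1.1,2,0.6,FALSE
bmi,under_30,1,1,1,0.6,TRUE
bmi,30_plus,1.2,0.9,1.6,0.4,FALSE
nsaid,nonuser,1,1,1,0.6,TRUE
nsaid,user,0.64,0.52,0.79,0.4,FALSE
statin,nonuser,1,1,1,0.6,TRUE
statin,user,0.57,0.43,0.75,0.4,FALSE
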