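factor,level,rr,ci_low,ci_high,prevalence,is_reference
sgerd,rarely_or_never,1,1,1,0.55,TRUE
sgerd,less_than_weekly,1.6,1.2,2.1,0.2,FALSE
sgerd,weekly_to_daily,4.5,3.5,5.8,0.18,FALSE
sgerd,more_than_daily,6.5,4.8,8.8,0.07,FALSE
bmi,under_25,1,1,1,0.32,TRUE
bmi,25_to_30,1.5,1.3,1.8,0.35,FALSE
bmi,30_to_35,2.4,1.9,3,0.2,FALSE
bmi,35_plus,3.1,2.4,4,0.13,FALSE
smoking,never,1,1,1,0.55,TRUE
smoking,former,1.6,1.4,1.9,0.3,FALSE
smoking,current,2.3,1.9,2.8,0.15,FALSE
family_history,none,1,1,1,0.94,TRUE
family_history,first_degree_be_or_eac,3,1.5,6,0.06,FALSE
physical_activity,low,1,1,1,0.4,TRUE
physical_activity,moderate,0.85,0.7,1.03,0.4,FALSE
physical_activity,high,0.68,0.5,0.93,0.2,FALSE
nsaid,nonuser,1,1,1,0.7,TRUE
nsaid,user,0.64,0.52,0.79,0.3,FALSE
statin,nonuser,1,1,1,0.67,TRUE
statin,user,0.57,0.43,0.75,0.33,FALSE
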