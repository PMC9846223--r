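variable,level,overall_n,overall_pct,healthy_n,healthy_pct,sick_n,sick_pct,note
mother_age,<20,2629,15.2,1281,15.1,1348,15.4,
mother_age,20-34,13263,76.9,6524,76.9,6739,76.9,
mother_age,35-49,1359,7.9,681,8.0,678,7.7,
education,no_education,1267,7.3,696,8.2,571,6.5,
education,primary_incomplete,2164,12.5,1074,12.7,1090,12.4,
education,primary_complete,2643,15.3,1364,16.1,1279,14.6,
education,secondary_incomplete,7507,43.5,3567,42.0,3940,45.0,
education,secondary_complete_plus,3670,21.3,1785,21.0,1885,21.5,
wealth,lowest,3319,19.2,1638,19.3,1681,19.2,
wealth,second,3353,19.4,1666,19.6,1687,19.2,
wealth,middle,3473,20.1,1691,19.9,1782,20.3,
wealth,fourth,3519,20.4,1696,20.0,1823,20.8,
wealth,highest,3587,20.8,1795,21.2,1792,20.4,
living_children,1,5992,34.7,2860,33.7,3132,35.7,
living_children,2-3,9302,53.9,4615,54.4,4687,53.5,
living_children,4+,1957,11.3,1011,11.9,946,10.8,
child_death,no,15524,90.0,7644,90.1,7880,89.9,
child_death,yes,1727,10.0,842,9.9,885,10.1,
sex,female,8882,51.5,4603,54.2,4279,48.8,
sex,male,8369,48.5,3883,45.8,4486,51.2,
chw_visit,no,14193,82.3,7163,84.4,7030,80.2,
chw_visit,yes,3058,17.7,1323,15.6,1735,19.8,
ds_counseling,no,13011,75.4,6574,77.5,6437,73.4,
ds_counseling,yes,4240,24.6,1912,22.5,2328,26.6,
distance,<=5km,8146,47.2,3980,46.9,4166,47.5,
distance,5+km,9105,52.8,4506,53.1,4599,52.5,
anc4,no,12540,72.7,6360,74.9,6180,70.5,
anc4,yes,4711,27.3,2126,25.1,2585,29.5,
facility_delivery,no,8254,47.8,4147,48.9,4107,46.9,
facility_delivery,yes,8997,52.2,4339,51.1,4658,53.1,
pnc,no,9765,56.6,4877,57.5,4888,55.8,
pnc,yes,7486,43.4,3609,42.5,3877,44.2,
mat_careseek,no,14188,35.0,7399,36.8,6789,34.0,printed row is internally inconsistent: counts sum to the full sample although the stated denominator is the N=4713 complication subset
mat_careseek,yes,3063,65.0,1087,63.2,1976,66.0,printed row is internally inconsistent: counts sum to the full sample although the stated denominator is the N=4713 complication subset
knowledge_cat,0,589,3.4,301,3.5,288,3.3,
knowledge_cat,1-4,13618,78.9,6919,81.5,6699,76.4,
knowledge_cat,5+,3044,17.6,1266,14.9,1778,20.3,
neo_careseek_any,no,,,,,457,5.2,reported only for the sick-neonate subset
neo_careseek_any,yes,,,,,8308,94.8,reported only for the sick-neonate subset
neo_careseek_provider,none,,,,,457,5.2,reported only for the sick-neonate subset
neo_careseek_provider,unqualified,,,,,5110,58.3,reported only for the sick-neonate subset
neo_careseek_provider,qualified,,,,,3198,36.5,reported only for the sick-neonate subset
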