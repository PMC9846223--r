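equation,predictor,level,scale,estimate,ci_low,ci_high,stars
anc4,mother_age,20-34,or,1.24,1.06,1.45,**
anc4,mother_age,35-49,or,1.04,0.79,1.36,
anc4,education,primary_incomplete,or,1.18,0.89,1.58,
anc4,education,primary_complete,or,1.36,1.03,1.79,*
anc4,education,secondary_incomplete,or,1.73,1.33,2.24,**
anc4,education,secondary_complete_plus,or,2.62,2.00,3.45,**
anc4,wealth,second,or,1.14,0.95,1.36,
anc4,wealth,middle,or,1.30,1.09,1.55,**
anc4,wealth,fourth,or,1.80,1.52,2.14,**
anc4,wealth,highest,or,3.40,2.86,4.04,**
anc4,living_children,2-3,or,0.78,0.70,0.88,**
anc4,living_children,4+,or,0.51,0.40,0.64,**
anc4,child_death,yes,or,1.30,1.10,1.53,**
anc4,distance,<=5km,or,1.25,1.14,1.39,**
anc4,chw_visit,yes,or,2.89,2.57,3.25,**
facility_delivery,anc4,yes,or,2.53,2.27,2.83,**
facility_delivery,mother_age,20-34,or,1.25,1.07,1.45,**
facility_delivery,mother_age,35-49,or,1.99,1.56,2.53,**
facility_delivery,education,primary_incomplete,or,0.94,0.75,1.17,
facility_delivery,education,primary_complete,or,1.08,0.86,1.34,
facility_delivery,education,secondary_incomplete,or,1.39,1.14,1.70,**
facility_delivery,education,secondary_complete_plus,or,1.88,1.50,2.35,**
facility_delivery,wealth,second,or,1.45,1.25,1.68,**
facility_delivery,wealth,middle,or,1.90,1.64,2.20,**
facility_delivery,wealth,fourth,or,2.59,2.22,3.01,**
facility_delivery,wealth,highest,or,3.52,2.99,4.14,**
facility_delivery,living_children,2-3,or,0.63,0.56,0.70,**
facility_delivery,living_children,4+,or,0.34,0.28,0.41,**
facility_delivery,child_death,yes,or,0.93,0.80,1.09,
facility_delivery,distance,<=5km,or,1.12,1.02,1.23,*
facility_delivery,chw_visit,yes,or,0.91,0.81,1.03,
pnc,facility_delivery,yes,or,41.22,35.56,47.77,**
pnc,anc4,yes,or,1.46,1.27,1.68,**
pnc,mother_age,20-34,or,0.99,0.81,1.20,
pnc,mother_age,35-49,or,1.62,1.15,2.26,**
pnc,education,primary_incomplete,or,1.68,1.23,2.30,**
pnc,education,primary_complete,or,1.55,1.14,2.10,**
pnc,education,secondary_incomplete,or,1.85,1.40,2.45,**
pnc,education,secondary_complete_plus,or,2.22,1.63,3.02,**
pnc,wealth,second,or,1.13,0.92,1.38,
pnc,wealth,middle,or,1.11,0.91,1.35,
pnc,wealth,fourth,or,1.27,1.04,1.56,*
pnc,wealth,highest,or,1.39,1.12,1.73,**
pnc,living_children,2-3,or,1.00,0.85,1.16,
pnc,living_children,4+,or,0.73,0.56,0.95,*
pnc,child_death,yes,or,0.97,0.79,1.20,
pnc,distance,<=5km,or,0.97,0.79,1.20,
pnc,chw_visit,yes,or,1.04,0.89,1.22,
mat_careseek,pnc,yes,or,1.96,1.58,2.44,**
mat_careseek,facility_delivery,yes,or,1.67,1.35,2.07,**
mat_careseek,anc4,yes,or,1.46,1.20,1.76,**
mat_careseek,mother_age,20-34,or,1.29,1.00,1.67,
mat_careseek,mother_age,35-49,or,1.49,0.99,2.22,
mat_careseek,education,primary_incomplete,or,1.05,0.73,1.51,
mat_careseek,education,primary_complete,or,0.95,0.66,1.35,
mat_careseek,education,secondary_incomplete,or,1.22,0.87,1.71,
mat_careseek,education,secondary_complete_plus,or,1.27,0.87,1.86,
mat_careseek,wealth,second,or,0.92,0.71,1.18,
mat_careseek,wealth,middle,or,1.15,0.89,1.47,
mat_careseek,wealth,fourth,or,1.09,0.84,1.42,
mat_careseek,wealth,highest,or,1.00,0.76,1.33,
mat_careseek,living_children,2-3,or,1.00,0.81,1.23,
mat_careseek,living_children,4+,or,1.21,0.87,1.66,
mat_careseek,child_death,yes,or,1.08,0.84,1.40,
mat_careseek,distance,<=5km,or,1.08,0.92,1.40,
mat_careseek,chw_visit,yes,or,1.01,0.83,1.23,
knowledge,pnc,yes,beta,0.46,0.35,0.57,**
knowledge,facility_delivery,yes,beta,-0.35,-0.46,-0.24,**
knowledge,anc4,yes,beta,0.24,0.15,0.33,**
knowledge,mother_age,20-34,beta,0.21,0.10,0.33,**
knowledge,mother_age,35-49,beta,0.22,0.03,0.41,*
knowledge,education,primary_incomplete,beta,0.11,-0.05,0.28,
knowledge,education,primary_complete,beta,0.22,0.06,0.39,**
knowledge,education,secondary_incomplete,beta,0.26,0.11,0.42,**
knowledge,education,secondary_complete_plus,beta,0.47,0.29,0.64,**
knowledge,wealth,second,beta,0.10,-0.01,0.22,
knowledge,wealth,middle,beta,-0.03,-0.15,0.08,
knowledge,wealth,fourth,beta,0.07,-0.05,0.19,
knowledge,wealth,highest,beta,0.08,-0.05,0.21,
knowledge,living_children,2-3,beta,0.16,0.07,0.25,**
knowledge,living_children,4+,beta,0.39,0.23,0.54,**
knowledge,child_death,yes,beta,0.01,-0.11,0.13,
knowledge,chw_visit,yes,beta,-0.03,-0.13,0.07,
knowledge,ds_counseling,yes,beta,0.12,0.02,0.21,*
neo_careseek,knowledge,1-4,or,1.24,0.96,1.62,
neo_careseek,knowledge,5+,or,1.44,1.09,1.90,*
neo_careseek,mat_careseek,yes,or,1.06,0.96,1.18,
neo_careseek,pnc,yes,or,1.18,1.03,1.34,*
neo_careseek,facility_delivery,yes,or,1.30,1.14,1.48,**
neo_careseek,anc4,yes,or,1.26,1.14,1.40,**
neo_careseek,mother_age,20-34,or,0.91,0.79,1.04,
neo_careseek,mother_age,35-49,or,1.07,0.85,1.34,
neo_careseek,education,primary_incomplete,or,0.83,0.66,1.03,
neo_careseek,education,primary_complete,or,1.03,0.83,1.28,
neo_careseek,education,secondary_incomplete,or,0.91,0.75,1.11,
neo_careseek,education,secondary_complete_plus,or,0.85,0.68,1.05,
neo_careseek,wealth,second,or,1.31,1.13,1.52,**
neo_careseek,wealth,middle,or,1.48,1.28,1.73,**
neo_careseek,wealth,fourth,or,1.53,1.31,1.78,**
neo_careseek,wealth,highest,or,1.49,1.27,1.75,**
neo_careseek,living_children,2-3,or,1.00,0.90,1.12,
neo_careseek,living_children,4+,or,0.91,0.76,1.10,
neo_careseek,child_death,yes,or,0.84,0.72,0.98,*
neo_careseek,sex,male,or,1.20,1.10,1.31,**
neo_careseek,distance,<=5km,or,1.13,1.03,1.23,**
neo_careseek,chw_visit,yes,or,1.04,0.93,1.16,
neo_careseek,ds_counseling,yes,or,1.12,1.01,1.25,*
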