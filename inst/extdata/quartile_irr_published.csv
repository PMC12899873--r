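cohort,quartile,median_score,score_min,score_max,cases,person_years,irr_multivariable,ci_low,ci_high
CAVAS,Q1,0.98,-9.90,3.04,190,22787,1.00,NA,NA
CAVAS,Q2,4.57,3.04,5.96,201,23926,0.98,0.81,1.20
CAVAS,Q3,7.32,5.96,8.91,231,24566,1.07,0.88,1.30
CAVAS,Q4,11.02,8.91,24.6,331,25327,1.45,1.21,1.74
HEXA,Q1,-0.23,-13.7,1.90,429,2050,1.00,NA,NA
HEXA,Q2,3.51,1.90,4.87,492,2047,1.13,0.99,1.28
HEXA,Q3,6.19,4.87,7.64,546,2064,1.23,1.08,1.40
HEXA,Q4,9.49,7.64,24.0,723,2075,1.58,1.40,1.78
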