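cohort,n_total,n_female,n_cases,person_years,incidence_rate_per_1000py,mean_age,mean_followup_years
CAVAS,16665,10503,953,96605,9.9,58.2,5.8
HEXA,51206,34670,2190,205454,8.7,53.0,4.9
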