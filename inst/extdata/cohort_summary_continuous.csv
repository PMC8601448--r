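cohort,age_group,variable,group,mean,sd,n
NACC,70s,age,TCP,74.07,2.68,83
NACC,70s,age,non-TCP,74.34,2.75,161
NACC,70s,education,TCP,16.49,2.37,83
NACC,70s,education,non-TCP,14.33,3.54,161
NACC,80s,age,TCP,82.82,2.56,22
NACC,80s,age,non-TCP,83.44,2.70,81
NACC,80s,education,TCP,16.55,2.54,22
NACC,80s,education,non-TCP,14.35,3.55,81
90plus,90s,age,TCP,94.06,2.60,35
90plus,90s,age,non-TCP,93.75,2.62,73
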