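cohort,age_group,variable,level,tcp,non_tcp
NACC,70s,sex,female,59,91
NACC,70s,sex,male,24,70
NACC,80s,sex,female,13,48
NACC,80s,sex,male,9,33
90plus,90s,sex,female,22,47
90plus,90s,sex,male,13,26
90plus,90s,education,HS-or-less,3,12
90plus,90s,education,some-college-to-grad,18,29
90plus,90s,education,graduate-plus,14,32
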