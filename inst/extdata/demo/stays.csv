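resident_id,facility_id,entry_date,exit_date,sex,birth_year
p1,f1,2019-01-01,2019-12-31,F,1931
p2,f1,2018-12-01,2019-12-31,M,1929
p3,f1,2019-01-01,2019-12-31,F,1935
p4,f1,2019-01-01,2019-06-30,M,1927
p5,f1,2019-07-01,2019-12-31,F,1933
p6,f1,2019-03-01,2019-03-10,M,1940
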