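record_id,resident_id,facility_id,dispense_date,atc_code,route,n_packages,units_per_package,prescriber_id
d00,p2,f1,2018-12-20,J01MA01,oral,1,10,g1
d01,p2,f1,2019-02-03,J01XE01,oral,1,21,g1
d02,p2,f1,2019-02-05,J01MA01,oral,1,10,g1
d03,p1,f1,2019-05-12,J01XX01,oral,1,1,g2
d04,p3,f1,2019-08-05,J01MA02,oral,1,10,g2
d05,p3,f1,2019-06-01,J01MA02,oral,1,10,g2
d06,p4,f1,2019-01-15,J01CR02,oral,2,14,g3
d07,p4,f1,2019-02-10,J01CA04,oral,1,14,g3
d08,p1,f1,2019-11-20,J01CA04,oral,2,14,g2
d09,p5,f1,2019-12-05,J01DC02,oral,1,14,g1
d10,p2,f1,2019-07-10,J01DD04,IV,1,3,g1
d11,p3,f1,2019-04-15,J01FA09,oral,1,14,g2
d12,p6,f1,2019-03-05,J01FG01,oral,1,21,g3
d13,p5,f1,2019-08-20,J01CA04,oral,1,14,g1
d14,p2,f1,2019-11-25,J01CA04,oral,1,14,g1
d15,p1,f1,2019-03-20,J01EE01,oral,1,20,g2
d16,p1,f1,2019-11-20,M01AE01,oral,1,20,g2
d17,p3,f1,2019-05-20,J01CR02,oral,1,14,g2
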