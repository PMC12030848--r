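class,s1_train,s1_test,s2_train,s2_test,s3_train,s3_test
River,3033,1011,1059,354,1030,344
Buildup,3056,1019,1940,647,1663,555
Sugarcane,3078,1027,4426,1476,3343,1115
Tree,3040,1014,3921,1308,2394,799
Barren,3007,1003,2538,847,4576,1526
Pond,2968,990,1648,550,1219,407
Other,3243,1081,2715,906,1971,658
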