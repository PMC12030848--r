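class,area_2019,area_2021,area_2023,rate_2019_2021,rate_2021_2023,rate_2019_2023
River,230.21,211.60,276.64,-8.08,30.74,20.17
Buildup,383.80,391.26,635.19,1.94,62.34,65.50
Sugarcane,443.96,458.48,547.25,3.27,19.36,23.27
Tree,908.91,841.86,1225.16,-7.38,45.53,34.79
Barren,785.82,914.34,438.64,16.35,-52.03,-44.18
Pond,140.27,89.78,78.24,-35.99,-12.85,-44.22
Other,732.37,718.01,424.19,-1.96,-40.92,-42.08
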