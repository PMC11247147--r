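# Transcribed reference table: projected 2027 prevalence of cardiovascular complications per 100,000 patients with CKD.
region,country,heart_failure,myocardial_infarction,stroke,total
Americas,Brazil,7595,3107,2825,13527
Americas,Canada,9852,6874,9276,26001
Americas,Colombia,9678,8132,1709,19519
Americas,Mexico,4947,6703,3962,15612
Americas,USA,13114,6505,12876,32494
Europe,Belgium,6272,6181,4498,16951
Europe,Denmark,11979,10753,9710,32442
Europe,France,4666,3662,5923,14252
Europe,Germany,1307,474,954,2735
Europe,Greece,13243,11611,7686,32540
Europe,Hungary,25826,5524,9591,40941
Europe,Italy,13496,11758,8641,33895
Europe,Netherlands,6744,14469,8059,29273
Europe,Poland,14501,17762,44838,77101
Europe,Romania,13560,15608,38915,68083
Europe,Spain,10555,4691,4196,19441
Europe,Sweden,11569,5508,8011,25090
Europe,Türkiye,5536,2052,2279,9868
Europe,UK,4707,4267,7827,16800
Asia-Pacific/Middle East,Australia,20621,5288,5005,30914
Asia-Pacific/Middle East,China,4987,13676,9253,27916
Asia-Pacific/Middle East,India,11259,10878,5228,27365
Asia-Pacific/Middle East,Israel,3074,2628,2856,8559
Asia-Pacific/Middle East,Japan,19769,21231,7365,48366
Asia-Pacific/Middle East,Philippines,13100,13275,8838,35213
Asia-Pacific/Middle East,Saudi Arabia,6150,3989,1880,12020
Asia-Pacific/Middle East,Singapore,5829,9499,5914,21243
Asia-Pacific/Middle East,South Korea,5795,1995,7251,15041
Asia-Pacific/Middle East,Taiwan,10759,4687,2949,18395
Asia-Pacific/Middle East,Thailand,6071,16662,6929,29661
Asia-Pacific/Middle East,UAE Emirati,8017,5816,5068,18902
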