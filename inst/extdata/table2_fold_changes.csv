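mirna,alias,p_ra_hc,fold_ra_hc,rank_ra_hc,p_fdr_hc,fold_fdr_hc,p_fdr_ra,fold_fdr_ra
hsa-miR-103a-3p,hsa-miR-103a-3p,0.0064,3.96,1,0.0238,7.68,0.1223,1.97
hsa-miR-155,hsa-miR-155,0.0002,2.47,2,0.0115,1.98,0.3627,-1.25
hsa-miR-29b,hsa-miR-29b,0.0648,1.91,3,0.8636,-1.55,0.0754,-2.96
hsa-miR-132,hsa-miR-132,0.0016,1.90,4,0.0687,1.37,0.2530,-1.39
hsa-miR-26b-3p,hsa-miR-26b-3p,0.0010,1.88,5,0.0024,2.28,0.2530,1.21
hsa-miR-152,hsa-miR-152,0.0038,1.83,6,0.1309,1.97,0.4981,1.08
hsa-miR-19a,hsa-miR-19a,0.0732,1.73,7,0.0205,1.55,0.9662,-1.11
hsa-Let-7a,hsa-Let-7a,0.0569,1.73,7,0.2086,1.17,0.2358,-1.47
hsa-miR-19b,hsa-miR-19b,0.0260,1.67,9,0.1169,1.34,0.4091,-1.24
hsa-miR-146a-5p,hsa-miR-146a-5p,0.0083,1.54,10,0.0031,1.99,0.3408,1.29
hsa-miR-451,hsa-miR-451,0.0076,1.53,11,0.0127,1.56,0.7031,1.02
RNU44,RNU44,0.0120,1.52,12,0.0162,1.30,0.9157,-1.17
hsa-miR-125a-5p,hsa-miR-125a-5p,0.0272,1.30,13,0.0553,1.50,0.7508,1.15
hsa-miR-222,hsa-miR-222,0.0796,1.29,14,0.2154,1.20,0.4587,-1.07
hsa-miR-107,hsa-miR-107,0.0576,1.28,15,0.2481,-1.02,0.4587,-1.31
hsa-miR-29c,hsa-miR-29c,0.2428,1.28,16,0.1457,1.11,0.8159,-1.15
hsa-Let-7e,hsa-Let-7e,0.0502,1.27,17,0.5837,-1.20,0.0987,-1.53
hsa-miR-21,hsa-miR-21,0.0261,1.24,18,0.0924,1.22,0.7832,-1.16
hsa-miR-223,hsa-miR-223,0.0115,1.22,19,0.5487,1.03,0.5115,-1.82
hsa-miR-26b-5p,hsa-miR-26b-5p,0.1191,1.21,20,0.6744,-1.45,0.0277,-1.76
hsa-miR-323-3p,hsa-miR-323-3p,0.1123,1.17,21,0.2033,1.12,0.9831,-1.04
hsa-miR-26a,hsa-miR-26a,0.1849,1.14,22,0.1159,1.33,0.8822,1.16
hsa-miR-29a,hsa-miR-29a,0.1031,1.14,23,0.6174,-1.29,0.1124,1.46
hsa-miR-15a,hsa-miR-15a,0.5594,1.11,24,0.8292,-1.56,0.1223,-1.72
hsa-miR-150,hsa-miR-150,0.6104,1.10,25,0.4100,1.20,0.7669,1.09
hsa-miR-34a*,hsa-miR-34a-3p,0.1065,1.06,26,0.0495,-1.84,0.0262,-1.94
hsa-miR-221,hsa-miR-221,0.1842,1.06,27,0.9914,-1.37,0.2356,-1.45
hsa-miR-24,hsa-miR-24,0.2956,-1.05,28,0.8651,1.03,0.9831,1.04
hsa-miR-18a,hsa-miR-18a,0.7615,-1.07,29,0.7639,-1.85,0.1124,-1.72
U6,U6,0.8069,-1.11,30,0.0001,-1.59,0.0625,-1.43
hsa-miR-125a-3p,hsa-miR-125a-3p,0.1654,-1.20,31,0.6178,-1.10,0.4847,1.10
hsa-miR-16,hsa-miR-16,0.9950,-3.94,32,0.8276,-1.24,0.2802,-1.23
hsa-miR-346,hsa-miR-346,0.0001,-8.70,33,0.0001,-20.00,0.0338,-2.32
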