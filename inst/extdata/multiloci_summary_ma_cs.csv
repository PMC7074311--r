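trait,order,parent,cofactor,favorable,k,factors,ideotype,n,mean,sd,ci_lo,ci_hi,adj_r2_pct,p_value
SEDW,1,CS,e7_VviAGL11,b,1,2,b,217,0.0412,0.0256,0.03776,0.04462,52.11,0
SEDW,2,MA,chr13_14817494_1,a,2,4,ba,122,0.0363,0.0233,0.03208,0.04045,53.71,0
SEDW,3,MA,chr9_5511355_1,b,3,8,bab,70,0.0321,0.0184,0.02773,0.03653,54.38,0
SEDW,4,MA,chr13_810814_1,a,4,16,baba,43,0.0316,0.0213,0.02505,0.03815,55.41,0
SEDW,5,CS,chr4_19816331_1,b,5,32,babab,29,0.0308,0.0234,0.02187,0.03968,55.98,0
SEDN,1,MA,chr2_5144635_1,a,1,2,a,267,2.6574,1.1862,2.5145,2.8003,9.15,0
SEDN,2,CS,e7_VviAGL11,b,2,4,ab,100,2.4220,1.0830,2.208,2.637,14.63,0
SEDN,3,MA,chr1_4720746_1,a,3,8,aba,44,2.1980,1.0930,1.866,2.530,17.09,0
SEDN,4,CS,chr1_20882467_1,b,4,16,abab,19,1.8610,0.9310,1.412,2.310,19.46,0
SEDN,5,CS,chr12_1741069_1,b,5,32,ababb,13,1.7950,0.8360,1.289,2.300,21.72,0
SEDA,1,CS,e7_VviAGL11,b,1,2,b,218,0.05056,0.02813,0.04681,0.05432,43.87,0
SEDA,2,MA,chr2_5330875_1,a,2,4,ba,119,0.05004,0.02631,0.04526,0.05481,48.83,0
SEDA,3,MA,chr9_1387529_1,a,3,8,baa,71,0.04831,0.02505,0.04238,0.05424,49.06,0
SEDA,4,MA,chr13_14790761_1,b,4,16,baab,34,0.03942,0.01989,0.03248,0.04636,49.82,0
SEDA,5,CS,chr2_5222338_1,a,5,32,baaba,15,0.03227,0.01562,0.02362,0.04092,51.92,0
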