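trait,parent,chrom,position_cm,cofactor,lod,pct_var,mean_a,mean_b,sd_a,sd_b,lod_2015,lod_2016,lod_2017,lod_2018,stable,significance
SEDW,MA,9,33.108,chr9_5511355_1,2.26,1.7,0.0867,0.0753,NA,NA,0.98,0.93,0.72,3.28,no,significant
SEDW,MA,13,1.345,chr13_810814_1,1.96,1.5,0.0740,0.0870,NA,NA,1.99,0.89,1.54,1.93,yes,suggestive
SEDW,MA,13,61.553,chr13_14817494_1,2.39,1.8,0.0742,0.0886,NA,NA,0.53,1.5,2.5,1.88,yes,suggestive
SEDW,CS,4,63.423,chr4_19816331_1,2.33,0.9,0.0885,0.0740,NA,NA,2.24,1.03,1.78,1.47,yes,suggestive
SEDW,CS,14,10.51,chr14_3367810_1,2.06,0.8,0.0758,0.0880,NA,NA,0.19,1.02,0.93,1.49,no,suggestive
SEDW,CS,18,96.474,e7_VviAGL11,90.4,48.4,0.1052,0.0410,0.0320,0.0256,38.85,73.61,58.93,46.78,yes,significant
SEDN,MA,1,23.448,chr1_4720746_1,4.03,2.8,2.8760,3.2148,NA,NA,1.95,2.85,0.88,1.91,yes,significant
SEDN,MA,2,31.857,chr2_5144635_1,12.81,9.2,2.6574,3.3845,NA,NA,5.41,6.59,0.73,16.5,yes,significant
SEDN,MA,8,53.979,chr8_16567159_1,2.06,1.4,3.2588,2.9028,NA,NA,1.5,0.74,0.89,0.64,no,suggestive
SEDN,MA,13,1.345,chr13_810814_1,2.49,1.7,2.8896,3.1877,NA,NA,1.19,0.74,0.24,2.03,no,suggestive
SEDN,CS,1,68.878,chr1_20882467_1,2.82,1.9,3.2313,2.8568,NA,NA,0.24,4.49,0.59,0.85,no,suggestive
SEDN,CS,2,30.109,chr2_5443648_1,2.48,1.6,3.2588,2.9172,NA,NA,1.61,0.36,1.3,3.7,no,suggestive
SEDN,CS,7,99.657,chr7_24375532_1,2.46,1.6,3.1993,2.8989,NA,NA,0.79,0.98,0.13,2.97,no,suggestive
SEDN,CS,12,4.672,chr12_1741069_1,2.95,1.9,3.2576,2.8558,NA,NA,0.94,3.43,2.35,0.43,yes,suggestive
SEDN,CS,12,65.968,chr12_22397742_1,2.76,1.8,2.8865,3.2123,NA,NA,2.02,1.43,0.35,1.73,yes,suggestive
SEDN,CS,18,96.474,e7_VviAGL11,5.27,3.5,3.2574,2.7010,NA,NA,3.51,1.87,0.61,4.84,yes,significant
SEDA,MA,2,32.691,chr2_5330875_1,4.32,3.2,0.0797,0.0968,NA,NA,0.25,3.57,0.18,8.96,yes,significant
SEDA,MA,9,8.439,chr9_1387529_1,2.56,1.9,0.0815,0.0944,NA,NA,2.28,1.10,0.72,2.24,yes,suggestive
SEDA,MA,13,61.22,chr13_14790761_1,2.27,1.7,0.0938,0.0826,NA,NA,0.13,2.15,5.15,1.06,yes,suggestive
SEDA,CS,2,27.274,chr2_5222338_1,3.95,1.6,0.0788,0.0933,NA,NA,0.74,0.09,1.43,4.42,no,significant
SEDA,CS,8,50.684,chr8_17020635_1,2.66,1.1,0.0878,0.0972,NA,NA,0.02,1.79,1.92,2.52,yes,suggestive
SEDA,CS,10,54.671,chr10_8168185_1,3.15,1.3,0.0827,0.0827,NA,NA,1.16,0.92,0.59,2.89,no,significant
SEDA,CS,14,10.51,chr14_3367810_1,1.93,0.8,0.0878,0.0834,NA,NA,0.33,0.48,1.22,0.89,no,suggestive
SEDA,CS,18,96.474,e7_VviAGL11,76.08,42.5,0.1107,0.0506,NA,NA,20.74,43.37,53.98,38.99,yes,significant
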