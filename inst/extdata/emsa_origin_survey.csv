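origin,ratio,kd,kd_se,acs_status
ARS728,-0.112,8.38,1.11,confirmed
ARS1325,-0.079,63.04,1.943,confirmed
ARS911,-0.046,87.33,2.205,confirmed
ARS1329,0.004,76.8,4.002,confirmed
ARS1631,0.018,26.79,1.192,confirmed
ARS512,0.022,55.06,1.556,confirmed
ARS1413,0.022,418.9,21.76,confirmed
ARS920,0.057,8.652,1.116,confirmed
ARS604,0.072,61.03,2.888,confirmed
ARS1405,0.09,97.18,4.689,confirmed
ARS1004,0.114,92.27,2.121,confirmed
ARS1323,0.139,58.62,3.024,confirmed
ARS818,0.161,93.96,4.237,confirmed
ARS716,0.169,39.21,5.439,confirmed
ARS214,0.198,41.33,1.409,confirmed
ARS822,0.201,260.3,13.74,confirmed
ARS809,0.216,ND,,confirmed
ARS1215,0.229,55.8,2.055,predicted
ARS720,0.242,33.9,2.715,confirmed
ARS416,0.551,35.07,1.223,confirmed
ARS824,0.871,38.11,2.034,predicted
ARS423,0.872,6.757,1.214,confirmed
ARS1332,0.876,35.29,0.8786,confirmed
ARS516,0.878,27.76,1.439,confirmed
ARS105,0.885,ND,,confirmed
ARS1625,0.889,8.669,1.295,confirmed
ARS201,0.903,20.13,1.65,predicted
ARS1601,0.916,32.75,1.287,predicted
ARS1521,0.94,90.13,2.361,confirmed
ARS1528,0.947,ND,,confirmed
ARS1123,0.948,12.35,1.231,confirmed
ARS1529.5,0.98,191.6,18.98,confirmed
ARS1011,0.982,11.07,0.8141,confirmed
ARS1021,1.003,17.9,0.8416,confirmed
ARS1420,1.003,17.82,1.48,confirmed
ARS422,1.003,9.853,1.168,confirmed
ARS317,1.014,7.223,0.6519,confirmed
ARS514,1.06,4.116,0.7319,confirmed
ARS1320,1.067,20.95,1.617,confirmed
ARS219.5,1.273,ND,,confirmed
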