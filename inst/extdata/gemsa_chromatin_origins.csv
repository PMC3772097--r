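origin,ratio,kd,kd_se,group
ARS1015,0.81,63.13,4.3,new_tested
ARS815,0.81,,,new_untested
ARS1114,0.82,33.29,2.4,new_tested
ARS1307,0.82,83.7,3.0,new_tested
ARS305,0.83,33.07,2.3,new_tested
ARS1513,0.83,56.30,4.7,new_tested
ARS428,0.83,91.6,4.2,new_tested
ARS447,0.84,,,new_untested
ARS1116,0.84,,,new_untested
ARS609,0.86,,,new_untested
ARS1332,0.88,35.29,0.88,prior_complex
ARS516,0.88,27.76,1.4,prior_dna_dependent
ARS105,0.88,ND,,prior_chromatin_dependent
ARS1521,0.94,90.13,2.36,prior_chromatin_dependent
ARS1528,0.95,ND,,prior_chromatin_dependent
ARS1529.5,0.98,191.6,18.98,prior_chromatin_dependent
ARS1005,1.03,ND,,new_tested
ARS1016,1.05,,,new_untested
ARS1618.5,1.11,,,new_untested
ARS219.5,1.27,ND,,prior_chromatin_dependent
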