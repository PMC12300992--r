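compound_id,isoform,ki_nm
cpd_1,hCA_I,7.3
cpd_1,hCA_II,1.4
cpd_1,hCA_IX,67.7
cpd_1,hCA_XII,716.5
cpd_2,hCA_I,1023.0
cpd_2,hCA_II,11.6
cpd_2,hCA_IX,713.1
cpd_2,hCA_XII,30.6
cpd_3,hCA_I,>100000
cpd_3,hCA_II,>100000
cpd_3,hCA_IX,>100000
cpd_3,hCA_XII,>100000
cpd_4,hCA_I,36.2
cpd_4,hCA_II,6.8
cpd_4,hCA_IX,2523.8
cpd_4,hCA_XII,603.0
cpd_5,hCA_I,>100000
cpd_5,hCA_II,>100000
cpd_5,hCA_IX,>100000
cpd_5,hCA_XII,>100000
cpd_6,hCA_I,>100000
cpd_6,hCA_II,7050.3
cpd_6,hCA_IX,>100000
cpd_6,hCA_XII,>100000
cpd_7,hCA_I,2858.1
cpd_7,hCA_II,9.8
cpd_7,hCA_IX,6826.7
cpd_7,hCA_XII,350.9
cpd_8,hCA_I,1204.8
cpd_8,hCA_II,23.9
cpd_8,hCA_IX,715.4
cpd_8,hCA_XII,832.5
cpd_9,hCA_I,212.6
cpd_9,hCA_II,443.6
cpd_9,hCA_IX,728.5
cpd_9,hCA_XII,568.4
cpd_10,hCA_I,31589
cpd_10,hCA_II,>100000
cpd_10,hCA_IX,>100000
cpd_10,hCA_XII,>100000
cpd_11,hCA_I,665.6
cpd_11,hCA_II,16.4
cpd_11,hCA_IX,73.7
cpd_11,hCA_XII,49.4
cpd_12,hCA_I,1076.3
cpd_12,hCA_II,151.4
cpd_12,hCA_IX,313.2
cpd_12,hCA_XII,648.1
AAZ,hCA_I,250.0
AAZ,hCA_II,12.1
AAZ,hCA_IX,25.3
AAZ,hCA_XII,5.7
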