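system,class_label,expected_neg,expected_pos,expected_total,observed_neg,observed_pos,observed_total,observed_pos_pct,printed_spared_neg,printed_spared_pos,printed_spared_total,note
KTIRADS,2,227,7,234,348,17,365,4.7,121,10,131,
KTIRADS,3,2102,191,2293,2607,220,2827,7.8,505,29,534,
KTIRADS,4,2381,323,2704,2381,323,2704,11.9,NA,NA,NA,
KTIRADS,5,429,149,578,429,149,578,25.8,NA,NA,NA,
ATA,benign,0,0,0,53,0,53,0,NA,NA,NA,never_expected
ATA,very_low,9,0,9,12,0,12,0,3,0,3,
ATA,low,2681,225,2906,3319,266,3585,7.4,638,41,679,
ATA,intermediate,1135,146,1281,1135,146,1281,11.4,NA,NA,NA,
ATA,high,851,234,1085,851,234,1085,21.6,NA,NA,NA,
AACE,low,828,60,888,1481,103,1584,6.5,653,43,696,
AACE,intermediate,1405,145,1550,3016,306,3322,9.2,1611,161,1772,
AACE,high,1268,300,1568,1268,300,1568,19.1,NA,NA,NA,
EUTIRADS,2,8,0,8,57,0,57,0,8,0,49,spared_neg_inconsistent
EUTIRADS,3,1054,94,1148,1760,161,1921,8.4,706,67,773,
EUTIRADS,4,1991,179,2170,2680,248,2928,8.5,689,69,758,
EUTIRADS,5,1194,272,1466,1268,300,1568,19.1,74,28,102,
ACRTIRADS,TR1,8,0,8,19,0,19,0,11,0,11,
ACRTIRADS,TR2,18,0,18,226,3,229,1.3,208,3,211,
ACRTIRADS,TR3,166,14,180,571,34,605,5.6,405,20,425,
ACRTIRADS,TR4,2472,245,2717,3093,301,3394,8.9,621,56,667,spared_total_inconsistent
ACRTIRADS,TR5,1856,193,2227,1856,193,2227,16.7,NA,NA,NA,counts_inconsistent_with_total
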