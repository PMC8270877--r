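system,total_fna,sensitivity_pct,specificity_pct,ppv_pct,ppv_pm_pct,npv_pct,npv_pm_pct,spared_n,spared_pct
KTIRADS,6474,94.5,14.8,11.5,0.8,95.6,1.3,665,10.3
ATA,6016,84.5,19.5,7.7,0.3,94.1,1.7,682,11.3
AACE,6474,50.1,50.3,8.4,2.7,91.7,0.8,2468,38.1
EUTIRADS,6474,80.6,20.7,10.8,2.0,89.9,0.7,1682,25.9
ACRTIRADS,6474,72.7,31.7,8.9,1.0,93.0,1.3,1324,20.6
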