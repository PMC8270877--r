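system,expected_total,observed_total,spared_total
KTIRADS,5809,6474,665
ATA,5281,6016,682
AACE,4006,6474,2468
EUTIRADS,4792,6474,1682
ACRTIRADS,5150,6474,1324
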