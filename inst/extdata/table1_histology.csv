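label,n,percent
papillary_classic,166,46.8
follicular_variant_papillary,97,27.3
medullary,12,3.4
other_well_differentiated,70,19.8
insular,3,0.8
other_poorly_differentiated,5,1.4
metastasis_other_cancer,2,0.5
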