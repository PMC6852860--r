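trait,marker,additive,dominance,reproducible
DTRW2,LEP,-8.67,-2.43,1
DTRW3,LEP,-7.32,8.09,1
DTRW3,FABP4_3691,-18.44,-16.76,1
DTRW3,GHR,6.75,6.31,1
DTRW4,CAPN1_316,-13.36,-33.04,1
DTRW5,LEP,-10.91,5.77,1
W2-W3 FP,FABP4_2834,-4.37,-0.02,1
W2-W3 FP,LGB,3.45,2.47,1
W2-W3 FP,GHR,2.88,3.52,1
W4-W5 FP,GHR,-3.45,9.25,1
FW,CAPN1_316,21.66,18.13,1
W2-W3 DMI,CAST,-13.89,16.67,1
W2-W3 DMI,GHR,17.23,15.66,1
TDMI,LEP,-26.01,159.0,1
TDMI,IGF1,55.5,-94.51,1
TDMI,GHR,155.2,-40.5,0
W1-W2 DDMI,FABP4_3533,0.13,-0.12,1
W4-W5 DDMI,MYF5,0.01,0.39,1
W4-W5 DDMI,GHR,0.16,-0.48,1
TDDMI,LEP,-0.71,-0.12,0
TDDMI,FABP4_3533,-0.14,-0.28,1
TDDMI,IGF1,0.14,-0.19,1
TDDMI,LGB,-0.19,-0.26,1
W2-W3 FCR,CAST,-0.16,0.18,1
W2-W3 FCR,GHR,0.21,0.22,1
W4-W5 FCR,FABP4_3533,-0.06,-0.77,1
TFCR,LEP,-0.18,0.19,1
TFCR,IGF1,-0.42,0.3,0
TFCR,CAPN1_316,-0.62,-0.56,1
W2-W3 ADWG,FABP4_2834,0.05,-0.01,1
W2-W3 ADWG,LGB,-0.04,-0.02,1
W2-W3 ADWG,GHR,-0.04,-0.03,1
W4-W5 ADWG,FABP4_3533,0.03,0.13,1
W4-W5 ADWG,GHR,0.06,-0.13,1
TADWG,CAPN1_316,0.05,0.04,1
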