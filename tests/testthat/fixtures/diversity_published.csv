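marker,chi2,Ho,He,Ne,PIC
LEP,92.452,0.6568,0.3432,1.5225,0.2843
FABP4_3691,5.098,0.6249,0.3751,1.6,0.3047
FABP4_2834,23.594,0.5128,0.4872,1.9501,0.3685
FABP4_3533,15.74,0.505,0.495,1.9802,0.3725
DGAT1,36.746,0.5002,0.4998,1.9992,0.3749
TG,19.207,0.7888,0.2112,1.2677,0.1889
IGF1,32.331,0.5072,0.4928,1.9716,0.3714
IGF1R,2.791,0.545,0.455,1.8349,0.3515
MYF5,13.132,0.5968,0.4032,1.6756,0.3219
LGB,27.858,0.5072,0.4928,1.9716,0.3714
CAPN1_316,4.182,0.5882,0.4118,1.7001,0.327
CAPN1_530,0.323,0.7178,0.2822,1.3931,0.2424
CAST,1.606,0.5098,0.4902,1.9616,0.3701
GHR,33.621,0.6568,0.3432,1.5225,0.2843
OLR1,112.861,0.5288,0.4712,1.8911,0.3602
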