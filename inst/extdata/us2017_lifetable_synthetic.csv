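# Synthetic stand-in for the 2017 US all-population life table (ages 60-85).
# Values reproduce the level and Gompertz-like age gradient of the published
# national annual death probabilities qx but were generated for this package;
# they are not a copy of the NVSS publication.
age,qx
60,0.008830
61,0.009526
62,0.010244
63,0.010970
64,0.011704
65,0.012518
66,0.013420
67,0.014331
68,0.015282
69,0.016371
70,0.017723
71,0.019276
72,0.020967
73,0.022808
74,0.024896
75,0.027333
76,0.030081
77,0.033036
78,0.036282
79,0.039958
80,0.044299
81,0.049378
82,0.054953
83,0.061146
84,0.068063
85,0.075800
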