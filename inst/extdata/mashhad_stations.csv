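site,station,lat,lon,As,Hg,Pb,Cr,Ni
north,1,4029710,727406,0.15,ND,0.83,0.415,1.22
north,2,4027701,728482,0.14,ND,0.415,0.565,0.9
north,3,4025335,724454,0.12,ND,0.705,0.97,3.2
north,4,4027198,721742,0.27,ND,1.065,6.03,1.2255
north,5,4025914,725243,0.15,ND,0.485,2.725,1.5556
north,6,4018132,735467,0.25,ND,0.705,3.65,1.885
north,7,4018221,735984,0.20,ND,0.365,17.67,0.45
south,8,4017602,736047,0.17,ND,0.36,0.36,0.795
south,9,4014001,733598,0.09,ND,0.525,0.535,0.395
south,10,4014963,733130,0.20,ND,0.485,3.825,1.09
south,11,4016330,740638,0.21,ND,0.385,8.245,0.185
south,12,4014951,743628,0.18,ND,0.31,8.265,1.27
south,13,4023448,728776,0.14,ND,0.59,6.41,1.31
south,14,4024096,731871,0.18,ND,0.395,10.21,0.36
east,15,4020529,737745,0.10,ND,0.33,0.68,0.28
east,16,4022731,739408,0.19,ND,0.515,11.17,0.23
east,17,4023714,732412,0.12,ND,0.375,23.25,1.715
east,18,4025587,735752,0.28,ND,0.625,0.47,1.815
east,19,4025452,734910,0.21,ND,0.495,0.565,0.35
east,20,402041,728081,0.15,ND,0.56,0.59,0.58
east,21,4023401,721575,0.16,ND,0.75,4.16,0.86
west,22,4024240,723377,0.16,0.2,0.54,2.415,1.715
west,23,4021934,723688,0.39,ND,1.33,6.34,13.145
west,24,4023475,726604,0.18,ND,0.31,7.51,0.4
west,25,4021665,730176,0.18,ND,0.625,0.315,3.05
west,26,4020791,733368,0.23,ND,0.53,1.185,2.96
west,27,4019883,732363,0.24,ND,0.64,4.455,1.405
west,28,4017836,732942,0.20,ND,0.745,5.56,2.47
center,29,4016239,733048,0.23,ND,0.505,4.08,1.49
center,30,4019093,730563,0.20,ND,0.54,2.525,1.145
center,31,4019123,734946,0.14,ND,0.56,1.59,1.51
center,32,4017372,734784,0.16,0.2,0.575,7.875,0.95
center,33,4019664,734467,0.13,ND,0.45,1.435,1.59
center,34,4018134,734290,0.20,0.1,0.81,19.5,3.63
center,35,4019632,735625,0.14,ND,0.635,0.4,1.19
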