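name,reference_ed,mu_0.25,mu_0.50,mu_0.75,mu_1.00,mu_1.25,mu_1.50,mu_2.00,mu_2.50,mu_3.00,mu_4.00,mu_5.00,mu_6.00,mu_8.00,mu_10.00,mu_12.50,mu_15.00,muen_0.25,muen_0.50,muen_0.75,muen_1.00,muen_1.25,muen_1.50,muen_2.00,muen_2.50,muen_3.00,muen_4.00,muen_5.00,muen_6.00,muen_8.00,muen_10.00,muen_12.50,muen_15.00
air,0.001,0.11412,0.08721,0.0738,0.06363,0.05688,0.05175,0.04446,0.03987,0.03573,0.0306,0.02727,0.02493,0.02187,0.01998,0.01845,0.01719,0.02799,0.0297,0.02898,0.02781,0.02664,0.02547,0.0234,0.02178,0.02043,0.01854,0.0171,0.0162,0.01485,0.01395,0.01332,0.01278
lung_surrogate,0.26,0.125532,0.095964,0.081224,0.070041,0.062618,0.056975,0.048956,0.043907,0.039351,0.033706,0.030041,0.027466,0.024098,0.022018,0.020334,0.018947,0.030789,0.032681,0.031895,0.030612,0.029327,0.028042,0.025766,0.023985,0.022501,0.020422,0.018838,0.017848,0.016363,0.015373,0.01468,0.014086
adipose,0.95,0.124898,0.095364,0.08066,0.06952,0.062128,0.056512,0.048534,0.043511,0.038984,0.033375,0.029735,0.027177,0.023833,0.021767,0.020095,0.018718,0.030633,0.032477,0.031674,0.030384,0.029098,0.027814,0.025544,0.023769,0.022291,0.020221,0.018645,0.01766,0.016183,0.015198,0.014507,0.013916
water,1,0.1268,0.0969,0.082,0.0707,0.0632,0.0575,0.0494,0.0443,0.0397,0.034,0.0303,0.0277,0.0243,0.0222,0.0205,0.0191,0.0311,0.033,0.0322,0.0309,0.0296,0.0283,0.026,0.0242,0.0227,0.0206,0.019,0.018,0.0165,0.0155,0.0148,0.0142
muscle,1.04,0.126166,0.096383,0.081546,0.070299,0.062834,0.057162,0.049103,0.044029,0.039453,0.033784,0.030104,0.027518,0.024137,0.022049,0.020358,0.018966,0.030944,0.032824,0.032022,0.030725,0.029429,0.028134,0.025844,0.024052,0.022559,0.020469,0.018877,0.017882,0.01639,0.015395,0.014698,0.014101
cartilage,1.1,0.126166,0.096432,0.081612,0.07037,0.062909,0.057238,0.049178,0.044103,0.039526,0.033853,0.030171,0.027583,0.024199,0.022109,0.020417,0.019024,0.030944,0.032841,0.032048,0.030756,0.029464,0.028171,0.025883,0.024093,0.0226,0.020511,0.018919,0.017924,0.016431,0.015436,0.01474,0.014143
trabecular_bone,1.18,0.128068,0.097705,0.0826,0.071168,0.063584,0.057823,0.049643,0.044494,0.039856,0.03411,0.030381,0.027762,0.024337,0.022222,0.020509,0.0191,0.031411,0.033274,0.032436,0.031104,0.02978,0.028459,0.026128,0.024306,0.022789,0.020667,0.019051,0.01804,0.016525,0.015515,0.014807,0.0142
cortical_bone,1.78,0.131238,0.100456,0.08509,0.073414,0.06566,0.059764,0.05138,0.0461,0.04133,0.03542,0.031582,0.028885,0.025356,0.023177,0.021413,0.019959,0.032188,0.034211,0.033413,0.032086,0.030752,0.029414,0.027042,0.025183,0.023632,0.02146,0.019804,0.01877,0.017217,0.016182,0.015459,0.014839
metal_surrogate,4,0.142016,0.110825,0.09492,0.082535,0.074262,0.067923,0.058841,0.053104,0.047837,0.041303,0.03704,0.034034,0.030096,0.027664,0.025702,0.024066,0.034832,0.037742,0.037274,0.036073,0.034781,0.03343,0.030969,0.029009,0.027353,0.025025,0.023226,0.022116,0.020435,0.019315,0.018556,0.017892
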