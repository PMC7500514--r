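"region","slope","slope_ci_lo","slope_ci_hi","slope_x_entryage","sxe_ci_lo","sxe_ci_hi","loss20","loss20_ci_lo","loss20_ci_hi","random_slope_sd","rssd_ci_lo","rssd_ci_hi","random_slope_p","sex_p"
"Caudal Middle Frontal",-0.556,-0.707,-0.398,-0.01,-0.034,0.013,-12.726,-14.891,-10.593,0.125,0.008,0.356,0.563,0.074
"Frontal Pole",-0.663,-0.871,-0.443,-0.01,-0.044,0.022,-14.831,-18.038,-11.681,0.458,0.197,0.656,0.076,0.479
"Lateral Orbitofrontal",-0.385,-0.508,-0.26,-0.011,-0.031,0.008,-9.546,-11.354,-7.719,0.108,0.003,0.288,0.887,0.125
"Medial Orbitofrontal",-0.363,-0.559,-0.178,-0.015,-0.042,0.012,-9.726,-12.093,-7.288,0.162,0.007,0.427,0.937,0.371
"Para-Central",-0.533,-0.686,-0.376,-0.002,-0.025,0.019,-11.065,-13.215,-8.933,0.173,0.005,0.36,0.912,0.044
"Pars Opercularis",-0.626,-0.751,-0.503,-0.005,-0.024,0.013,-13.394,-15.086,-11.692,0.154,0.024,0.303,0.347,0.026
"Pars Orbitalis",-0.737,-0.873,-0.597,0.002,-0.02,0.023,-14.437,-16.419,-12.487,0.001,0,0.291,1,0.367
"Pars Triangularis",-0.682,-0.812,-0.546,0.005,-0.016,0.026,-12.808,-14.795,-10.902,0.212,0.085,0.354,0.003,0.168
"Pre-Central",-0.631,-0.77,-0.486,-0.005,-0.027,0.016,-13.446,-15.498,-11.422,0.214,0.013,0.373,0.359,0.051
"Rostral Middle Frontal",-0.533,-0.69,-0.378,-0.003,-0.027,0.019,-11.261,-13.2,-9.235,0.043,0,0.109,0.633,0.024
"Superior Frontal",-0.548,-0.691,-0.401,-0.004,-0.026,0.017,-11.655,-13.585,-9.734,0.178,0.012,0.341,0.342,0.01
"Inferior Parietal",-0.677,-0.791,-0.563,-0.008,-0.026,0.008,-14.904,-16.545,-13.277,0.19,0.011,0.312,0.487,0.113
"Post-Central",-0.627,-0.749,-0.502,0,-0.018,0.017,-12.633,-14.291,-10.944,0.194,0.013,0.338,0.56,0.63
"Pre-Cuneus",-0.641,-0.75,-0.533,-0.015,-0.033,0.002,-15.256,-17.065,-13.451,0.186,0.012,0.323,0.548,0.015
"Superior Parietal",-0.592,-0.725,-0.457,-0.008,-0.027,0.01,-13.117,-14.86,-11.419,0.072,0.013,0.299,0.203,0.01
"Supra Marginal",-0.577,-0.688,-0.463,-0.014,-0.031,0.002,-13.769,-15.32,-12.304,0.209,0.023,0.303,0.143,0.015
"Banks Sup Temporal",-0.505,-0.621,-0.39,-0.02,-0.04,-0.001,-13.354,-15.374,-11.381,0.223,0.062,0.341,0.11,0.019
"Entorhinal",-0.379,-0.629,-0.141,-0.062,-0.095,-0.027,-17.423,-21.288,-13.676,0.782,0.613,0.965,3e-06,0.025
"Fusiform",-0.564,-0.674,-0.457,-0.029,-0.046,-0.012,-15.856,-17.708,-14.099,0.21,0.038,0.328,0.188,0.206
"Inferior Temporal",-0.525,-0.647,-0.399,-0.022,-0.041,-0.003,-14.035,-15.99,-12.156,0.267,0.099,0.388,0.105,0.062
"Middle Temporal",-0.536,-0.652,-0.42,-0.017,-0.035,-0.001,-13.515,-15.192,-11.896,0.266,0.168,0.353,0.019,0.069
"Para-Hippocampal",-0.395,-0.522,-0.27,-0.036,-0.057,-0.015,-13.702,-15.93,-11.561,0.341,0.224,0.445,0.004,0.033
"Superior Temporal",-0.66,-0.786,-0.535,-0.006,-0.024,0.011,-14.25,-15.852,-12.696,0.224,0.057,0.341,0.172,0.021
"Temporal Pole",-0.545,-0.738,-0.357,-0.042,-0.073,-0.013,-17.623,-20.96,-14.605,0.598,0.475,0.721,1e-08,0.3
"Transverse Temporal",-1.206,-1.376,-1.032,0.013,-0.013,0.038,-22.089,-24.551,-19.577,0.211,0.024,0.422,0.374,0.004
"Cuneus",-0.624,-0.758,-0.492,0.011,-0.012,0.033,-10.844,-13.146,-8.562,0.213,0.028,0.399,0.152,0.128
"Lateral Occipital",-0.743,-0.869,-0.616,0.006,-0.015,0.026,-13.958,-15.979,-12.028,0.257,0.103,0.361,0.068,0.433
"Lingual",-0.618,-0.736,-0.502,0.006,-0.012,0.024,-11.457,-13.374,-9.581,0.34,0.245,0.446,4e-04,0.101
"Peri-calcarine",-0.674,-0.899,-0.446,0.032,0.003,0.063,-8.33,-11.149,-5.44,0.49,0.277,0.668,0.016,0.616
"Caudal Anterior Cingulate",-0.282,-0.407,-0.154,-0.012,-0.03,0.005,-7.575,-9.296,-5.864,0.005,0.004,0.29,0.992,0.01
"Isthmus Cingulate",-0.437,-0.566,-0.309,-0.018,-0.041,0.005,-11.589,-13.941,-9.262,0.328,0.216,0.432,0.002,0.026
"Posterior Cingulate",-0.544,-0.672,-0.415,-0.026,-0.047,-0.004,-15.013,-17.032,-12.996,0.2,0.018,0.325,0.457,0.005
"Rostral Anterior Cingulate",-0.289,-0.439,-0.144,0.001,-0.022,0.022,-5.709,-7.796,-3.663,0.021,0.001,0.093,0.9,0.013
"Accumbens",-1.439,-1.75,-1.142,0.007,-0.034,0.047,-27.643,-32.031,-23.398,0.429,0.105,0.843,0.063,0.956
"Amygdala",-0.383,-0.517,-0.25,-0.024,-0.043,-0.003,-11.455,-13.621,-9.269,0.481,0.392,0.578,6e-14,0.573
"Caudate",-0.585,-0.718,-0.45,0.021,-0.002,0.044,-8.305,-10.606,-5.956,0.463,0.385,0.555,3e-12,0.568
"Hippocampus",-0.784,-0.904,-0.666,-0.04,-0.061,-0.018,-21.999,-24.339,-19.656,0.441,0.366,0.518,1e-13,0.286
"Insula",-0.499,-0.623,-0.374,-0.008,-0.028,0.011,-11.262,-13.373,-9.342,0.307,0.198,0.423,0.003,0.016
"Pallidum",0.069,-0.024,0.161,-0.013,-0.029,0.003,-0.703,-2.446,0.991,0.203,0.065,0.316,0.23,0.986
"Putamen",-0.639,-0.748,-0.529,0.031,0.016,0.046,-7.85,-9.386,-6.318,0.326,0.254,0.405,1e-05,0.697
"Thalamus",-0.832,-0.92,-0.745,0.008,-0.006,0.021,-15.409,-16.777,-14.043,0.24,0.17,0.304,3e-04,0.385
"Ventral DC",-0.516,-0.593,-0.438,0.006,-0.006,0.018,-9.409,-10.632,-8.18,0.21,0.146,0.276,0.001,0.016
"Brain Stem",-0.411,-0.461,-0.362,0,-0.007,0.007,-8.268,-9.028,-7.493,0.112,0.042,0.164,0.075,0.607
"Cerebellum Cortex",-0.494,-0.572,-0.418,0,-0.011,0.012,-9.818,-10.96,-8.654,0.147,0.027,0.219,0.193,0.827
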