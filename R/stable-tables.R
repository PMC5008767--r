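# Standardized-quantile lookup tables for the stable quantile initializer.
# Generated from the package's own numerical stable CDF by
# data-raw/make_quantile_tables.R; do not edit by hand.
.qtab_alpha <- c(0.5, 0.6, 0.7, 0.8, 0.9, 1, 1.1, 1.2, 1.3, 1.4, 1.5, 1.6, 1.7, 1.8, 1.9, 2)
.qtab_beta <- c(0, 0.25, 0.5, 0.75, 1)
.qtab_nu_alpha <- matrix(c(49.587437, 44.333379, 34.290826, 29.764172, 27.937931, 25.668623, 22.457842, 18.485265, 16.009482, 15.134387, 14.893767, 14.009232, 11.723902, 10.125078, 9.582583, 10.479083, 9.965299, 8.801883, 7.479258, 6.480086, 7.928492, 7.608806, 6.874376, 6.270575, 5.921142, 6.313752, 6.109509, 5.635172, 5.225937, 5.135825, 5.222869, 5.092535, 4.785625, 4.517752, 4.456054, 4.450851, 4.369468, 4.175875, 4.010192, 3.968464, 3.886470, 3.838126, 3.724014, 3.629411, 3.603164, 3.465625, 3.439854, 3.380818, 3.332943, 3.319158, 3.149795, 3.138836, 3.114597, 3.095422, 3.091285, 2.914029, 2.911176, 2.905241, 2.901634, 2.903890, 2.739382, 2.739543, 2.740429, 2.742935, 2.747783, 2.609914, 2.610456, 2.612094, 2.614856, 2.618753, 2.512818, 2.513012, 2.513593, 2.514557, 2.515894, 2.438664, 2.438664, 2.438664, 2.438664, 2.438664),
  nrow = 16, byrow = TRUE, dimnames = list(.qtab_alpha, .qtab_beta))
.qtab_nu_beta <- matrix(c(-0.000000, 0.465992, 0.843315, 0.970522, 0.984745, -0.000000, 0.455271, 0.768713, 0.935083, 0.960735, 0.000000, 0.386527, 0.690270, 0.883199, 0.920671, -0.000000, 0.341476, 0.634347, 0.824225, 0.857877, 0.000000, 0.302639, 0.572566, 0.769905, 0.818341, -0.000000, 0.268033, 0.513429, 0.699185, 0.761653, -0.000000, 0.236280, 0.456018, 0.624141, 0.693285, -0.000000, 0.206288, 0.399237, 0.547287, 0.621021, 0.000000, 0.177093, 0.342164, 0.470342, 0.545892, -0.000000, 0.147892, 0.284798, 0.394341, 0.468577, 0.000000, 0.118444, 0.228152, 0.319927, 0.389523, 0.000000, 0.089525, 0.173629, 0.247655, 0.309138, 0.000000, 0.062561, 0.122688, 0.178327, 0.228118, -0.000000, 0.038632, 0.076566, 0.113168, 0.147915, 0.000000, 0.017940, 0.035799, 0.053499, 0.070965, 0.000000, 0.000000, 0.000000, 0.000000, 0.000000),
  nrow = 16, byrow = TRUE, dimnames = list(.qtab_alpha, .qtab_beta))
.qtab_iqr <- matrix(c(2.567666, 3.051464, 4.507601, 6.600270, 9.093520, 2.324208, 2.621975, 3.527840, 4.789851, 6.222852, 2.180128, 2.382507, 2.994907, 3.832951, 4.761422, 2.091069, 2.237293, 2.669868, 3.257615, 3.903464, 2.035167, 2.143917, 2.456015, 2.881128, 3.349932, 2.000000, 2.081036, 2.307843, 2.620058, 2.968580, 1.977705, 2.037127, 2.201459, 2.431559, 2.693246, 1.963074, 2.005556, 2.123201, 2.291603, 2.487683, 1.952758, 1.982222, 2.064681, 2.185765, 2.330636, 1.944735, 1.964446, 2.020433, 2.104896, 2.208984, 1.937866, 1.950446, 1.986724, 2.042924, 2.114325, 1.931547, 1.939037, 1.960933, 1.995681, 2.041151, 1.925476, 1.929453, 1.941207, 1.960244, 1.985825, 1.919513, 1.921209, 1.926262, 1.934574, 1.945985, 1.913606, 1.914020, 1.915261, 1.917321, 1.920191, 1.907745, 1.907745, 1.907745, 1.907745, 1.907745),
  nrow = 16, byrow = TRUE, dimnames = list(.qtab_alpha, .qtab_beta))
.qtab_median <- matrix(c(0.000000, 0.060877, 0.279429, 0.658716, 1.198109, 0.000000, 0.077627, 0.271981, 0.580997, 0.996638, 0.000000, 0.088873, 0.262060, 0.519743, 0.853269, -0.000000, 0.095509, 0.250487, 0.468534, 0.742705, 0.000000, 0.098311, 0.237596, 0.423838, 0.652470, 0.000000, 0.097957, 0.223492, 0.383478, 0.575630, 0.000000, 0.095035, 0.208179, 0.345981, 0.507961, 0.000000, 0.090031, 0.191620, 0.310271, 0.446671, 0.000000, 0.083321, 0.173764, 0.275502, 0.389775, 0.000000, 0.075179, 0.154540, 0.240960, 0.335742, 0.000000, 0.065780, 0.133853, 0.206001, 0.283289, -0.000000, 0.055212, 0.111556, 0.169997, 0.231236, 0.000000, 0.043481, 0.087431, 0.132278, 0.178381, 0.000000, 0.030507, 0.061154, 0.092072, 0.123387, 0.000000, 0.016114, 0.032245, 0.048412, 0.064632, 0.000000, 0.000000, 0.000000, 0.000000, 0.000000),
  nrow = 16, byrow = TRUE, dimnames = list(.qtab_alpha, .qtab_beta))
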