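{
  "P": [0.82645, 3.0312, 26.844, 0.22028, 22.807, 30.438, 5.7443, 9.6769, 1809.6],
  "S": [0.56596, 0.06717, 1.151, 0.03181, 0.97227, 0.037697, 0.024872, 0.60515, 258.52],
  "Q": [1.6273, 0.58209, 0.65218, 14.988, 17.705, 272.67, 11.981, 56.946, 4.9391, 34.691, 4.779, 18.819, 61.511, 1.3297, 8.4207, 11.72, 14.013, 11.867, 9.5381, 1.7108, 4.6155, 23.779, 39.778, 3.0976, 1.5401, 0.9762, 13.822, 1368600, 0.50903, 150.6, 9.3893, 134.06, 15.778, 2.4818, 8.9587, 40.718, 14.545, 376.12, 351.21, 27.191, 133.91, 9.7889, 14.225],
  "R": [1.6354, 1.6833, 1.8982, 2.3757, 2.2303, 1.5392, 2.674, 3.5452, 1.4626, 1.3153, 1.8499, 3.0102, 4.9999, 1.1567, 1.8104, 2.117, 2.049, 1.8588, 2.2855, 3.3169, 2.3944, 2.9639, 1.7128, 2.0704, 0.60901, 1.3191, 4.0316, 1.8207, 1.9367, 1.3081, 1.9267, 1.9118, 2.3397, 1.9367, 1.7976, 1.3055, 2.6053, 1.1819, 1.8328, 1.9916, 2.9068, 2.0699, 2.041]
}
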