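{
  "schema_version": 1,
  "type": "spt_thresholds",
  "k": [5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17, 18, 19, 20, 21, 22, 23, 24, 25, 26, 27, 28, 29, 30, 31, 32, 33, 34, 35, 36, 37, 38, 39, 40, 41, 42, 43, 44, 45],
  "Y_C": [0.61385199999999995, 0.61293200000000003, 0.60983600000000004, 0.60762799999999995, 0.60482599999999997, 0.60343000000000002, 0.59962000000000004, 0.59696499999999997, 0.59391799999999995, 0.58984000000000003, 0.58772400000000002, 0.57978300000000005, 0.57671099999999997, 0.57169599999999998, 0.56505700000000003, 0.55618100000000004, 0.55198999999999998, 0.54744099999999996, 0.53922099999999995, 0.53431799999999996, 0.52698299999999998, 0.52301799999999998, 0.51395199999999996, 0.51045700000000005, 0.50700400000000001, 0.495309, 0.49229200000000001, 0.48463499999999998, 0.48145300000000002, 0.47029500000000002, 0.463254, 0.45719700000000002, 0.45201200000000002, 0.446488, 0.44236999999999999, 0.43971300000000002, 0.43462200000000001, 0.42685699999999999, 0.42351100000000003, 0.41942499999999999, 0.41841800000000001],
  "Y_D": [0.66948300000000005, 0.66865699999999995, 0.66727700000000001, 0.66583899999999996, 0.66415199999999996, 0.66145200000000004, 0.65962299999999996, 0.65696500000000002, 0.65464, 0.64835500000000001, 0.64535399999999998, 0.64073500000000005, 0.63535799999999998, 0.63277799999999995, 0.628247, 0.62676200000000004, 0.61899099999999996, 0.61432299999999995, 0.60949399999999998, 0.60319199999999995, 0.59580900000000003, 0.59124100000000002, 0.58203199999999999, 0.57728800000000002, 0.571774, 0.566168, 0.55706699999999998, 0.55235199999999995, 0.54700099999999996, 0.54572500000000002, 0.535833, 0.53163400000000005, 0.52665499999999998, 0.52441099999999996, 0.51592400000000005, 0.51592400000000005, 0.51568099999999994, 0.50671299999999997, 0.50531300000000001, 0.50204499999999996, 0.50003699999999995],
  "meta": {
    "n_null": 100,
    "null_frames": 1000,
    "D": 0.25,
    "dt": 0.10000000000000001,
    "S1": 31,
    "confidence": 0.94999999999999996,
    "familywise": true,
    "seed": 1237
  }
}
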