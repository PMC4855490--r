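{
  "schema_version": 1,
  "type": "bpnn",
  "m": 29,
  "n_hidden": 5,
  "p": 3,
  "W1": [-3.1404383514207526, -5.5242556726333083, -1.9805423001207045, 0.63228258308708452, -4.1556915043735234, 13.030166617192808, -5.453363432952683, -3.7363807326900367, -2.4749133696228629, 15.159548553050632, 14.590363776771975, -8.3257099937725147, -5.8098628764332334, -2.2386936434161759, 16.193228565990513, 13.031450670231576, -10.386081735902298, -5.8620520044348172, -1.6348441448432007, 13.373308310626831, 7.0873747749284126, -11.707765529215781, -5.2977443600342546, -0.28012788511037773, 5.9701478090372841, 2.5381646511074147, -11.333086014794842, -5.3690073964913472, 0.56107146729951352, 0.47341837358223349, -1.2803828791200063, -11.470549916138607, -4.8952561905363581, 2.0808261418152214, -4.8613638450541377, -0.95590649689670493, -10.236884319408835, -3.4051230828486423, 2.2190829240128647, -4.0358020319992898, -1.4874517096137114, -8.1726450317709656, -2.3357597811203821, 2.2747135320056096, -3.3957844030174456, -2.2213913486152976, -6.8422542855601938, -2.2714912524804203, 1.7223828963217707, -2.6298279676000842, -1.0901467038770818, -4.2458527070330527, -0.80697074800216873, 1.4148895240580848, -0.90343511847955338, -0.21069330810414097, -2.5721230601381673, -0.76645524183556346, 1.5759328469563036, 0.27582093296635668, 0.79038652827491462, -2.6828895412943385, 0.11128236285410927, -0.16043760222561429, 1.4094057467196353, 1.7566141813202221, -1.7491470255991866, -0.15707743637666863, -0.49918088145556821, 3.4601912420662981, -0.11210159021560057, -0.37234299115909791, 1.0188132901063633, -0.48485489713572055, 0.73460154103935649, -1.2798422329764367, 0.14369743940781846, 0.98871463820986893, -0.4747602894434777, -0.91678140567579181, -0.087765263548619701, -0.18661463693751185, -0.23884196334069252, -0.018069340815520092, -1.6811741289715783, -1.5694450942320297, 0.19261101279508883, 0.075112325228358409, 0.3280670534503245, -2.5622611218756877, -1.34651905543853, 0.5104886149562613, 0.19103049471371816, -0.33740752923867245, -1.7149891494343843, 0.67614494405264336, 1.0825310794964238, -0.36885410902629728, -2.0400789488263973, 0.71925496892617891, -1.0860098507132796, 0.7538148815333362, -0.031002050786254332, -1.0927086479055326, 0.21849881492472742, -0.36436983519369892, -0.80677591005202243, -0.72472804982670491, -1.6651021471202363, 0.086485651772767527, -0.025967201789458286, -0.48796031923765326, -1.3883538610013626, -1.4850323896444977, -0.60529854578384734, 1.0796753008967712, 0.72247418516200956, -0.33650566629397172, -1.9376506278605279, 0.64286295382252512, 0.046950746323377729, 1.4968221894520624, 0.78087689720165065, -2.748388509393755, 0.28544059861195809, -0.24125676806304341, 3.4687482415001916, 1.3460885166233136, -1.6530549777081318, -2.3098730626755963, 1.526475126957578, 0.56023002882521589, 0.49270998067548544, -2.2840053459082563, -0.59298580943302437, 3.3929342868556489, -0.01253430995664704, 0.2181492062117395, -2.9709628069452307, 2.3325276085698725, -3.3059086732898155, -0.11236972045272864, 0.36138990226397327, -3.2353219751695388, -1.5213476131744943, -2.8225301873795354, 9.3533785379701548, 5.4820766831235908, -3.1580745309603757, -1.1019784421909338],
  "W2": [0.88890163299665792, -1.8827778407675313, -1.0066838454356348, -1.6624824856825011, 2.5606969214384931, -3.0110384399352332, -2.8838098074897842, -4.8399932769582268, 2.5959317261611838, -0.60401231849640358, -5.8323530539462753, 1.2555071194130467, 1.9079129822149885, -1.7066565634305075, -1.071798025342434, -2.9871865880787589, 2.6538619559818333, -4.3684806684131798],
  "training_meta": {
    "seed": 1235,
    "eta": 0.10000000000000001,
    "alpha": 0.90000000000000002,
    "epochs_run": 64,
    "best_epoch": 44,
    "final_train_mse": 0.11114972562743766,
    "final_val_mse": 0.12008974259228659,
    "train_seed": 1236
  }
}
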