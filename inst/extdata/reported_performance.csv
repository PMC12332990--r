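dataset,side,n_pos,n_neg,sens_pct,spec_pct,acc_pct
validation,left,55,78,83.64,80.77,81.95
validation,right,24,109,75.00,94.50,90.98
test,left,63,70,69.84,82.86,76.69
test,right,22,111,68.18,90.09,86.47
extra_test_1,left,16,17,81.25,70.59,75.76
extra_test_1,right,7,26,71.43,96.15,90.91
extra_test_2,left,103,66,73.79,78.79,75.74
extra_test_2,right,30,139,63.33,89.93,85.21
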