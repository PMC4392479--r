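name,lambda,sigma_a2,sigma_s2,sigma_i2,B,phi,tau_phi,sho,lapse,n_trials
B115,1.409,0.113,102.130,0.523,14.849,0.175,0.064,0.157,0.094,NA
T055,1.226,0.001,11.248,0.043,16.014,0.253,0.351,0.118,0.078,NA
T057,0.810,0.031,74.478,0.027,15.060,0.156,0.093,0.020,0.075,NA
T058,1.087,0.000,17.612,0.000,15.875,0.025,0.276,-0.122,0.051,NA
T061,0.620,0.000,96.545,0.502,16.038,0.380,0.041,0.236,0.066,NA
T062,-0.098,0.000,49.361,0.619,15.761,0.139,0.047,0.518,0.083,NA
A065,2.047,0.000,37.685,0.207,15.729,0.147,0.092,-0.465,0.031,NA
A066,0.349,0.000,15.565,0.000,12.705,0.072,0.462,0.041,0.170,NA
A077,-2.739,0.197,128.586,22.801,9.253,0.184,0.031,0.886,0.001,NA
A078,-2.070,0.000,104.688,0.000,18.086,0.283,0.026,0.062,0.063,NA
A060,-1.542,0.000,54.786,0.000,15.416,0.010,0.115,0.180,0.245,NA
A062,2.258,0.296,156.860,0.486,16.839,0.527,0.076,0.466,0.119,NA
A083,-0.790,47.441,31.788,1.384,16.282,0.015,0.059,0.033,0.107,NA
A084,1.371,0.064,70.267,1.690,15.011,0.016,0.086,0.467,0.110,NA
meta_rat,1.227,0.001,57.614,0.043,16.042,0.221,0.109,0.065,0.102,47580
bilateral_fof,-4.144,62.423,237.642,1.754,22.013,0.082,0.039,0.737,0.010,1809
bilateral_ppc,1.331,0.531,42.175,0.000,14.860,0.512,0.175,-0.249,0.321,1569
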