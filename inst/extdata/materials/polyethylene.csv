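energy_keV,mu_over_rho_cm2_g,mu_en_over_rho_cm2_g,delta,beta
10.0,2.087360e+00,1.780784e+00,2.202111e-06,1.915300e-09
11.0,1.602170e+00,1.312618e+00,1.819927e-06,1.336458e-09
12.0,1.272391e+00,9.921992e-01,1.529244e-06,9.729237e-10
13.0,1.039962e+00,7.665516e-01,1.303024e-06,7.340297e-10
14.0,8.710887e-01,6.036391e-01,1.123526e-06,5.709180e-10
15.0,7.452037e-01,4.834175e-01,9.787160e-07,4.558513e-10
16.0,6.493029e-01,3.929644e-01,8.601996e-07,3.723632e-10
17.0,5.748860e-01,3.237239e-01,7.619761e-07,3.102932e-10
18.0,5.162328e-01,2.698952e-01,6.796639e-07,2.631555e-10
19.0,4.693941e-01,2.274610e-01,6.100031e-07,2.266853e-10
20.0,4.315810e-01,1.935848e-01,5.505278e-07,1.980030e-10
21.0,4.007535e-01,1.662408e-01,4.993449e-07,1.751046e-10
22.0,3.753171e-01,1.439832e-01,4.549816e-07,1.565363e-10
23.0,3.540866e-01,1.257272e-01,4.162781e-07,1.412606e-10
24.0,3.361863e-01,1.106432e-01,3.823109e-07,1.285311e-10
25.0,3.209577e-01,9.809267e-02,3.523378e-07,1.178005e-10
26.0,3.078978e-01,8.758034e-02,3.257561e-07,1.086607e-10
27.0,2.966167e-01,7.871974e-02,3.020728e-07,1.008025e-10
28.0,2.868084e-01,7.120703e-02,2.808815e-07,9.398817e-11
29.0,2.782299e-01,6.480175e-02,2.618444e-07,8.803293e-11
30.0,2.706861e-01,5.931229e-02,2.446790e-07,8.279118e-11
31.0,2.640181e-01,5.458550e-02,2.291479e-07,7.814685e-11
32.0,2.580936e-01,5.049933e-02,2.150499e-07,7.400595e-11
33.0,2.528029e-01,4.695454e-02,2.022141e-07,7.029227e-11
34.0,2.480553e-01,4.386965e-02,1.904940e-07,6.694359e-11
35.0,2.437749e-01,4.117747e-02,1.797642e-07,6.390875e-11
36.0,2.398980e-01,3.882233e-02,1.699160e-07,6.114537e-11
37.0,2.363707e-01,3.675794e-02,1.608554e-07,5.861806e-11
38.0,2.331473e-01,3.494563e-02,1.525008e-07,5.629713e-11
39.0,2.301886e-01,3.335296e-02,1.447805e-07,5.415749e-11
40.0,2.274609e-01,3.195265e-02,1.376319e-07,5.217784e-11
41.0,2.249358e-01,3.072098e-02,1.310001e-07,5.034010e-11
42.0,2.225908e-01,2.963536e-02,1.248362e-07,4.862922e-11
43.0,2.204067e-01,2.867637e-02,1.190974e-07,4.703225e-11
44.0,2.183667e-01,2.782779e-02,1.137454e-07,4.553791e-11
45.0,2.164558e-01,2.707594e-02,1.087462e-07,4.413633e-11
46.0,2.146610e-01,2.640930e-02,1.040695e-07,4.281883e-11
47.0,2.129705e-01,2.581803e-02,9.968814e-08,4.157776e-11
48.0,2.113740e-01,2.529375e-02,9.557774e-08,4.040636e-11
49.0,2.098622e-01,2.482927e-02,9.171641e-08,3.929864e-11
50.0,2.084267e-01,2.441838e-02,8.808444e-08,3.824924e-11
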