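energy_keV,mu_over_rho_cm2_g,mu_en_over_rho_cm2_g,delta,beta
10.0,3.111637e+00,2.781823e+00,2.142235e-06,2.855146e-09
11.0,2.369641e+00,2.057798e+00,1.770442e-06,1.976648e-09
12.0,1.858874e+00,1.560550e+00,1.487663e-06,1.421373e-09
13.0,1.496494e+00,1.209022e+00,1.267595e-06,1.056260e-09
14.0,1.232516e+00,9.542226e-01,1.092977e-06,8.078003e-10
15.0,1.035733e+00,7.654648e-01,9.521044e-07,6.335721e-10
16.0,8.860504e-01,6.229244e-01,8.368105e-07,5.081335e-10
17.0,7.701670e-01,5.134401e-01,7.412577e-07,4.156956e-10
18.0,6.790567e-01,4.280611e-01,6.611836e-07,3.461569e-10
19.0,6.064554e-01,3.605675e-01,5.934169e-07,2.928766e-10
20.0,5.479263e-01,3.065531e-01,5.355587e-07,2.513805e-10
21.0,5.002369e-01,2.628544e-01,4.857675e-07,2.185727e-10
22.0,4.609145e-01,2.271889e-01,4.426105e-07,1.922371e-10
23.0,4.281296e-01,1.978458e-01,4.049593e-07,1.707996e-10
24.0,4.005278e-01,1.735201e-01,3.719158e-07,1.531302e-10
25.0,3.770896e-01,1.532082e-01,3.427576e-07,1.384025e-10
26.0,3.570362e-01,1.361322e-01,3.168986e-07,1.260023e-10
27.0,3.397643e-01,1.216841e-01,2.938594e-07,1.154658e-10
28.0,3.248008e-01,1.093849e-01,2.732442e-07,1.064385e-10
29.0,3.117705e-01,9.885519e-02,2.547247e-07,9.864530e-11
30.0,3.003725e-01,8.979151e-02,2.380261e-07,9.187097e-11
31.0,2.903597e-01,8.195174e-02,2.229173e-07,8.594372e-11
32.0,2.815173e-01,7.514536e-02,2.092026e-07,8.072249e-11
33.0,2.736669e-01,6.921638e-02,1.967158e-07,7.609355e-11
34.0,2.666625e-01,6.403522e-02,1.853144e-07,7.196519e-11
35.0,2.603833e-01,5.949386e-02,1.748763e-07,6.826286e-11
36.0,2.547288e-01,5.550205e-02,1.652959e-07,6.492546e-11
37.0,2.496150e-01,5.198409e-02,1.564817e-07,6.190252e-11
38.0,2.449706e-01,4.887631e-02,1.483542e-07,5.915206e-11
39.0,2.407356e-01,4.612500e-02,1.408438e-07,5.663895e-11
40.0,2.368586e-01,4.368468e-02,1.338897e-07,5.433361e-11
41.0,2.332959e-01,4.151620e-02,1.274381e-07,5.221109e-11
42.0,2.300121e-01,3.958431e-02,1.214419e-07,5.025055e-11
43.0,2.269765e-01,3.785886e-02,1.158591e-07,4.843417e-11
44.0,2.241626e-01,3.631436e-02,1.106526e-07,4.674658e-11
45.0,2.215469e-01,3.492917e-02,1.057894e-07,4.517442e-11
46.0,2.191090e-01,3.368484e-02,1.012398e-07,4.370608e-11
47.0,2.168308e-01,3.256559e-02,9.697758e-08,4.233139e-11
48.0,2.146962e-01,3.155783e-02,9.297894e-08,4.104144e-11
49.0,2.126910e-01,3.064985e-02,8.922261e-08,3.982837e-11
50.0,2.108026e-01,2.983151e-02,8.568939e-08,3.868524e-11
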