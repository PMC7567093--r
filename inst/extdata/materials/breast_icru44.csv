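energy_keV,mu_over_rho_cm2_g,mu_en_over_rho_cm2_g,delta,beta
10.0,4.293502e+00,3.930075e+00,2.337439e-06,4.320842e-09
11.0,3.257179e+00,2.914561e+00,1.931767e-06,2.979927e-09
12.0,2.539337e+00,2.215444e+00,1.623221e-06,2.129589e-09
13.0,2.028243e+00,1.719953e+00,1.383100e-06,1.570122e-09
14.0,1.655313e+00,1.359895e+00,1.192571e-06,1.189895e-09
15.0,1.377186e+00,1.092508e+00,1.038862e-06,9.239703e-10
16.0,1.165692e+00,8.901227e-01,9.130620e-07,7.331966e-10
17.0,1.002063e+00,7.343360e-01,8.088023e-07,5.932020e-10
18.0,8.735052e-01,6.126070e-01,7.214317e-07,4.883707e-10
19.0,7.711144e-01,5.162034e-01,6.474899e-07,4.084340e-10
20.0,6.885719e-01,4.389262e-01,5.843597e-07,3.464782e-10
21.0,6.212882e-01,3.763102e-01,5.300314e-07,2.977354e-10
22.0,5.658124e-01,3.251132e-01,4.829419e-07,2.588251e-10
23.0,5.195896e-01,2.829062e-01,4.418599e-07,2.273470e-10
24.0,4.807168e-01,2.478402e-01,4.058053e-07,2.015741e-10
25.0,4.477555e-01,2.184943e-01,3.739902e-07,1.802426e-10
26.0,4.196024e-01,1.937671e-01,3.457749e-07,1.624132e-10
27.0,3.954011e-01,1.727972e-01,3.206363e-07,1.473774e-10
28.0,3.744787e-01,1.549059e-01,2.981427e-07,1.345940e-10
29.0,3.563011e-01,1.395540e-01,2.779356e-07,1.236448e-10
30.0,3.404400e-01,1.263101e-01,2.597154e-07,1.142026e-10
31.0,3.265429e-01,1.148294e-01,2.432298e-07,1.060072e-10
32.0,3.143012e-01,1.048398e-01,2.282655e-07,9.884455e-11
33.0,3.034598e-01,9.611823e-02,2.146408e-07,9.254307e-11
34.0,2.938107e-01,8.847854e-02,2.022006e-07,8.696516e-11
35.0,2.851829e-01,8.176526e-02,1.908113e-07,8.199967e-11
36.0,2.774349e-01,7.584806e-02,1.803579e-07,7.755596e-11
37.0,2.704485e-01,7.061739e-02,1.707406e-07,7.355962e-11
38.0,2.641246e-01,6.598085e-02,1.618725e-07,6.994906e-11
39.0,2.583794e-01,6.186030e-02,1.536778e-07,6.667298e-11
40.0,2.531417e-01,5.818941e-02,1.460899e-07,6.368839e-11
41.0,2.483508e-01,5.491145e-02,1.390505e-07,6.095907e-11
42.0,2.439553e-01,5.197706e-02,1.325079e-07,5.845446e-11
43.0,2.399110e-01,4.934393e-02,1.264164e-07,5.614852e-11
44.0,2.361794e-01,4.697598e-02,1.207355e-07,5.401893e-11
45.0,2.327271e-01,4.484226e-02,1.154291e-07,5.204645e-11
46.0,2.295248e-01,4.291618e-02,1.104650e-07,5.021441e-11
47.0,2.265467e-01,4.117478e-02,1.058143e-07,4.850836e-11
48.0,2.237703e-01,3.959820e-02,1.014513e-07,4.691565e-11
49.0,2.211754e-01,3.816917e-02,9.735271e-08,4.542525e-11
50.0,2.187443e-01,3.687269e-02,9.349755e-08,4.402744e-11
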