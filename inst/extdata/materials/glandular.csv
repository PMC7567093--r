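energy_keV,mu_over_rho_cm2_g,mu_en_over_rho_cm2_g,delta,beta
10.0,4.828025e+00,4.451675e+00,2.375001e-06,4.954038e-09
11.0,3.657460e+00,3.302773e+00,1.962810e-06,3.411747e-09
12.0,2.845585e+00,2.511433e+00,1.649306e-06,2.433213e-09
13.0,2.267140e+00,1.950291e+00,1.405326e-06,1.789472e-09
14.0,1.844951e+00,1.542319e+00,1.211735e-06,1.352217e-09
15.0,1.530090e+00,1.239206e+00,1.055556e-06,1.046684e-09
16.0,1.290707e+00,1.009679e+00,9.277346e-07,8.277468e-10
17.0,1.105550e+00,8.329311e-01,8.217995e-07,6.672974e-10
18.0,9.601200e-01,6.947761e-01,7.330249e-07,5.473219e-10
19.0,8.443154e-01,5.853320e-01,6.578949e-07,4.559749e-10
20.0,7.509674e-01,4.975803e-01,5.937502e-07,3.852839e-10
21.0,6.748742e-01,4.264616e-01,5.385489e-07,3.297565e-10
22.0,6.121464e-01,3.682960e-01,4.907026e-07,2.855107e-10
23.0,5.599021e-01,3.203275e-01,4.489604e-07,2.497894e-10
24.0,5.159899e-01,2.804596e-01,4.123265e-07,2.206072e-10
25.0,4.787803e-01,2.470818e-01,3.800001e-07,1.965106e-10
26.0,4.470220e-01,2.189458e-01,3.513315e-07,1.764190e-10
27.0,4.197425e-01,1.950755e-01,3.257888e-07,1.595177e-10
28.0,3.961774e-01,1.747017e-01,3.029338e-07,1.451849e-10
29.0,3.757196e-01,1.572131e-01,2.824020e-07,1.329400e-10
30.0,3.578822e-01,1.421205e-01,2.638890e-07,1.224077e-10
31.0,3.422648e-01,1.290325e-01,2.471385e-07,1.132897e-10
32.0,3.285173e-01,1.176403e-01,2.319337e-07,1.053412e-10
33.0,3.163509e-01,1.076900e-01,2.180901e-07,9.836597e-11
34.0,3.055302e-01,9.897017e-02,2.054499e-07,9.220724e-11
35.0,2.958622e-01,9.130390e-02,1.938776e-07,8.673837e-11
36.0,2.871872e-01,8.454296e-02,1.832562e-07,8.185635e-11
37.0,2.793720e-01,7.856271e-02,1.734843e-07,7.747669e-11
38.0,2.723052e-01,7.325798e-02,1.644737e-07,7.352958e-11
39.0,2.658923e-01,6.853978e-02,1.561473e-07,6.995697e-11
40.0,2.600535e-01,6.433257e-02,1.484375e-07,6.671025e-11
41.0,2.547205e-01,6.057187e-02,1.412850e-07,6.374849e-11
42.0,2.498348e-01,5.720201e-02,1.346372e-07,6.103704e-11
43.0,2.453459e-01,5.417536e-02,1.284478e-07,5.854639e-11
44.0,2.412101e-01,5.145108e-02,1.226757e-07,5.625130e-11
45.0,2.373893e-01,4.899410e-02,1.172840e-07,5.413006e-11
46.0,2.338505e-01,4.677419e-02,1.122401e-07,5.216393e-11
47.0,2.305645e-01,4.476519e-02,1.075147e-07,5.033667e-11
48.0,2.275058e-01,4.294443e-02,1.030816e-07,4.863412e-11
49.0,2.246517e-01,4.129217e-02,9.891714e-08,4.704391e-11
50.0,2.219822e-01,3.979122e-02,9.500003e-08,4.555520e-11
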