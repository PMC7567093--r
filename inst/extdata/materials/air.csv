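energy_keV,mu_over_rho_cm2_g,mu_en_over_rho_cm2_g,delta,beta
10.0,5.120000e+00,4.742000e+00,2.496361e-09,6.086082e-12
11.0,3.880143e+00,3.526379e+00,2.063109e-09,4.192980e-12
12.0,3.017544e+00,2.687575e+00,1.733584e-09,2.989098e-12
13.0,2.401381e+00,2.091568e+00,1.477137e-09,2.195764e-12
14.0,1.950704e+00,1.657324e+00,1.273654e-09,1.656271e-12
15.0,1.614000e+00,1.334000e+00,1.109494e-09,1.279028e-12
16.0,1.357620e+00,1.088653e+00,9.751412e-10,1.008617e-12
17.0,1.159051e+00,8.993388e-01,8.637929e-10,8.104408e-13
18.0,1.002890e+00,7.510745e-01,7.704819e-10,6.622909e-13
19.0,8.783888e-01,6.334071e-01,6.915129e-10,5.495422e-13
20.0,7.779000e-01,5.389000e-01,6.240904e-10,4.623402e-13
21.0,6.958779e-01,4.621825e-01,5.660683e-10,3.938960e-13
22.0,6.282012e-01,3.993385e-01,5.157772e-10,3.394251e-13
23.0,5.718078e-01,3.474315e-01,4.719020e-10,2.955222e-13
24.0,5.244001e-01,3.042255e-01,4.333961e-10,2.597284e-13
25.0,4.842303e-01,2.680013e-01,3.994178e-10,2.302395e-13
26.0,4.499519e-01,2.374244e-01,3.692842e-10,2.057124e-13
27.0,4.205156e-01,2.114500e-01,3.424364e-10,1.851340e-13
28.0,3.950949e-01,1.892534e-01,3.184134e-10,1.677302e-13
29.0,3.730323e-01,1.701787e-01,2.968325e-10,1.529031e-13
30.0,3.538000e-01,1.537000e-01,2.773735e-10,1.401859e-13
31.0,3.369639e-01,1.393957e-01,2.597671e-10,1.292081e-13
32.0,3.221465e-01,1.269317e-01,2.437853e-10,1.196662e-13
33.0,3.090366e-01,1.160334e-01,2.292343e-10,1.113176e-13
34.0,2.973807e-01,1.064716e-01,2.159482e-10,1.039685e-13
35.0,2.869711e-01,9.805494e-02,2.037846e-10,9.746260e-14
36.0,2.776361e-01,9.062271e-02,1.926205e-10,9.167295e-14
37.0,2.692323e-01,8.403976e-02,1.823493e-10,8.649546e-14
38.0,2.616400e-01,7.819199e-02,1.728782e-10,8.184428e-14
39.0,2.547578e-01,7.298277e-02,1.641263e-10,7.764809e-14
40.0,2.485000e-01,6.833000e-02,1.560226e-10,7.384723e-14
41.0,2.427929e-01,6.416373e-02,1.485045e-10,7.039147e-14
42.0,2.375725e-01,6.042419e-02,1.415171e-10,6.723799e-14
43.0,2.327833e-01,5.706017e-02,1.350114e-10,6.435039e-14
44.0,2.283774e-01,5.402755e-02,1.289443e-10,6.169761e-14
45.0,2.243134e-01,5.128830e-02,1.232771e-10,5.925302e-14
46.0,2.205550e-01,4.880950e-02,1.179755e-10,5.699370e-14
47.0,2.170706e-01,4.656258e-02,1.130087e-10,5.489983e-14
48.0,2.138325e-01,4.452269e-02,1.083490e-10,5.295418e-14
49.0,2.108161e-01,4.266815e-02,1.039717e-10,5.114175e-14
50.0,2.080000e-01,4.098000e-02,9.985446e-11,4.944942e-14
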