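# synthetic monomeric G4 SAXS curve (generated from the analytic cylinder
# form factor, D = 2.12 nm, L = 3.10 nm, 2% multiplicative noise; NOT
# experimental data)
# Q[1/nm]  I(Q)  sigma
5.000000e-02  1.033099e+02  1.997730e+00
5.267849e-02  9.789885e+01  1.997481e+00
5.550046e-02  9.843118e+01  1.997204e+00
5.847361e-02  9.821683e+01  1.996896e+00
6.160603e-02  1.001884e+02  1.996555e+00
6.490624e-02  9.801071e+01  1.996176e+00
6.838326e-02  9.772431e+01  1.995756e+00
7.204653e-02  9.625055e+01  1.995290e+00
7.590605e-02  1.042511e+02  1.994772e+00
7.997231e-02  9.660548e+01  1.994198e+00
8.425641e-02  9.993427e+01  1.993561e+00
8.877001e-02  9.943729e+01  1.992854e+00
9.352540e-02  9.659104e+01  1.992069e+00
9.853553e-02  9.559367e+01  1.991199e+00
1.038141e-01  1.045011e+02  1.990233e+00
1.093753e-01  1.013204e+02  1.989161e+00
1.152346e-01  1.018918e+02  1.987972e+00
1.214076e-01  9.819368e+01  1.986653e+00
1.279114e-01  9.609684e+01  1.985190e+00
1.347636e-01  9.868266e+01  1.983567e+00
1.419829e-01  9.789105e+01  1.981767e+00
1.495888e-01  9.929824e+01  1.979771e+00
1.576023e-01  9.634520e+01  1.977558e+00
1.660450e-01  9.866535e+01  1.975104e+00
1.749400e-01  1.009947e+02  1.972383e+00
1.843115e-01  9.699795e+01  1.969367e+00
1.941850e-01  9.859781e+01  1.966025e+00
2.045875e-01  9.651496e+01  1.962321e+00
2.155472e-01  9.597048e+01  1.958218e+00
2.270940e-01  9.900006e+01  1.953673e+00
2.392593e-01  9.726499e+01  1.948640e+00
2.520764e-01  9.465285e+01  1.943068e+00
2.655801e-01  9.738150e+01  1.936901e+00
2.798071e-01  9.736012e+01  1.930077e+00
2.947963e-01  9.464626e+01  1.922529e+00
3.105885e-01  9.475765e+01  1.914184e+00
3.272266e-01  9.500723e+01  1.904962e+00
3.447561e-01  9.418905e+01  1.894776e+00
3.632246e-01  9.154920e+01  1.883530e+00
3.826825e-01  9.617937e+01  1.871122e+00
4.031827e-01  9.289287e+01  1.857440e+00
4.247811e-01  9.303190e+01  1.842366e+00
4.475365e-01  9.217895e+01  1.825771e+00
4.715109e-01  9.204713e+01  1.807519e+00
4.967696e-01  9.097079e+01  1.787464e+00
5.233814e-01  8.819870e+01  1.765453e+00
5.514189e-01  8.867803e+01  1.741326e+00
5.809582e-01  8.831920e+01  1.714915e+00
6.120800e-01  8.525621e+01  1.686050e+00
6.448690e-01  8.158110e+01  1.654557e+00
6.794145e-01  8.085146e+01  1.620263e+00
7.158106e-01  7.965642e+01  1.582997e+00
7.541564e-01  7.877769e+01  1.542598e+00
7.945563e-01  7.519570e+01  1.498919e+00
8.371205e-01  7.194057e+01  1.451831e+00
8.819649e-01  7.130874e+01  1.401236e+00
9.292115e-01  6.784578e+01  1.347070e+00
9.789891e-01  6.647025e+01  1.289317e+00
1.031433e+00  6.266618e+01  1.228018e+00
1.086687e+00  5.844715e+01  1.163284e+00
1.144901e+00  5.402810e+01  1.095309e+00
1.206233e+00  5.148101e+01  1.024379e+00
1.270850e+00  4.660812e+01  9.508878e-01
1.338929e+00  4.347342e+01  8.753405e-01
1.410655e+00  4.040568e+01  7.983623e-01
1.486224e+00  3.507137e+01  7.206972e-01
1.565841e+00  3.267606e+01  6.432007e-01
1.649722e+00  2.855350e+01  5.668236e-01
1.738097e+00  2.449867e+01  4.925857e-01
1.831207e+00  2.093772e+01  4.215366e-01
1.929304e+00  1.755804e+01  3.547064e-01
2.032657e+00  1.474517e+01  2.930451e-01
2.141546e+00  1.175388e+01  2.373571e-01
2.256268e+00  9.078517e+00  1.882346e-01
2.377135e+00  7.333439e+00  1.460012e-01
2.504478e+00  5.525935e+00  1.106737e-01
2.638642e+00  4.148531e+00  8.195602e-02
2.779994e+00  3.044263e+00  5.927127e-02
2.928917e+00  2.081191e+00  4.183595e-02
3.085819e+00  1.463283e+00  2.876917e-02
3.251125e+00  9.751019e-01  1.921737e-02
3.425287e+00  6.339868e-01  1.246415e-02
3.608779e+00  4.034647e-01  7.989349e-03
3.802100e+00  2.699753e-01  5.449341e-03
4.005778e+00  2.325283e-01  4.574813e-03
4.220366e+00  2.454921e-01  5.021750e-03
4.446450e+00  3.237225e-01  6.250853e-03
4.684646e+00  3.721804e-01  7.525658e-03
4.935601e+00  3.906825e-01  8.082808e-03
5.200000e+00  3.712912e-01  7.432394e-03
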