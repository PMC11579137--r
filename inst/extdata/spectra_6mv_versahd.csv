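"energy_mev","0 cm","2 cm","4 cm","6 cm","8 cm","10 cm","12 cm","14 cm","16 cm","18 cm"
"0.100","3.745e-05","3.774e-05","7.440e-05","3.757e-04","1.024e-03","1.646e-03","2.339e-03","2.668e-03","3.893e-03","3.867e-03"
"0.200","7.489e-05","7.552e-05","1.488e-04","7.513e-04","2.047e-03","3.292e-03","4.679e-03","5.335e-03","7.786e-03","7.734e-03"
"0.300","1.123e-04","1.133e-04","2.232e-04","1.148e-03","3.071e-03","4.938e-03","7.018e-03","8.003e-03","1.168e-02","1.160e-02"
"0.425","2.387e-04","2.407e-04","4.743e-04","2.440e-03","6.526e-03","1.049e-02","1.491e-02","1.701e-02","2.482e-02","2.465e-02"
"0.600","1.352e-02","1.334e-02","1.404e-02","1.645e-02","2.080e-02","2.774e-02","3.539e-02","3.846e-02","5.012e-02","5.104e-02"
"0.850","6.548e-02","6.438e-02","6.727e-02","6.918e-02","7.424e-02","8.088e-02","8.965e-02","9.290e-02","1.053e-01","1.098e-01"
"1.200","1.890e-01","1.853e-01","1.938e-01","1.922e-01","1.890e-01","1.864e-01","1.832e-01","1.819e-01","1.762e-01","1.869e-01"
"1.650","3.249e-01","3.185e-01","3.330e-01","3.296e-01","3.241e-01","2.991e-01","2.758e-01","2.681e-01","2.327e-01","2.420e-01"
"2.200","4.246e-01","4.191e-01","4.320e-01","4.284e-01","4.069e-01","3.763e-01","3.370e-01","3.250e-01","2.634e-01","2.617e-01"
"2.875","4.435e-01","4.462e-01","4.421e-01","4.385e-01","4.107e-01","3.857e-01","3.505e-01","3.409e-01","2.769e-01","2.550e-01"
"3.675","3.821e-01","3.988e-01","3.643e-01","3.513e-01","3.154e-01","3.111e-01","2.906e-01","2.857e-01","2.444e-01","2.167e-01"
"4.625","3.206e-01","3.572e-01","2.789e-01","2.435e-01","2.208e-01","2.178e-01","2.140e-01","2.125e-01","2.059e-01","1.867e-01"
"6.075","1.446e-01","1.300e-01","1.288e-01","1.136e-01","1.007e-01","6.662e-02","6.111e-02","1.530e-02","1.482e-02","1.472e-02"
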