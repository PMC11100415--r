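-9.891210000000000280e-01
1.192166000000000059e+00
7.547700000000000520e-01
8.598810000000000064e-01
2.289909999999999890e+00
-5.430840000000000112e-01
9.529640000000000333e-01
-6.479650000000000132e-01
-3.035909999999999997e-01
8.553870000000000084e-01
-3.563129999999999908e-01
-7.057010000000000227e-01
4.107279999999999820e-01
-8.920000000000000151e-02
-1.488407999999999953e+00
-4.915539999999999909e-01
8.494490000000000096e-01
1.656679999999999930e+00
-3.738159999999999816e-01
-1.045729999999999993e-01
3.418320000000000247e-01
8.948030000000000150e-01
-2.388069999999999915e-01
-3.972260000000000235e-01
-1.050559000000000021e+00
-1.279765999999999959e+00
1.761284000000000072e+00
-1.696298000000000084e+00
-6.015570000000000084e-01
-7.396559999999999802e-01
1.564020000000000132e-01
-6.930600000000000649e-02
4.733879999999999755e-01
1.646400000000000086e-01
9.185060000000000446e-01
-6.414919999999999511e-01
8.414469999999999450e-01
-1.498825999999999992e+00
9.532519999999999882e-01
5.231130000000000502e-01
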