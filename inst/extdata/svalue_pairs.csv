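radionuclide,self_Gy_per_MBqh,neighbour_Gy_per_MBqh
32P,2.1437,0.218209
89Sr,1.9573,0.1720
153Sm,1.3444,0.03031
166Ho,2.1929,0.2092
177Lu,0.7782,0.01066
186Re,1.4561,0.0655
188Re,2.2032,0.2477
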