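image,n_boutons,precision,recall,f1,epb_precision,epb_recall,epb_f1
1,10,0.71,1.00,0.83,1.00,0.20,0.33
2,8,1.00,1.00,1.00,1.00,0.25,0.40
3,27,0.73,1.00,0.84,0.70,0.26,0.38
4,40,0.85,0.98,0.91,0.83,0.13,0.22
5,26,0.74,1.00,0.85,0.80,0.77,0.78
6,16,0.56,0.94,0.70,1.00,0.75,0.86
7,11,0.91,0.91,0.91,0.70,0.64,0.67
8,7,1.00,1.00,1.00,0.00,0.00,0.00
9,4,0.67,1.00,0.80,0.50,0.25,0.33
10,10,0.91,1.00,0.95,1.00,0.20,0.33
11,11,0.92,1.00,0.96,0.57,0.36,0.44
12,9,0.78,0.78,0.78,1.00,0.22,0.36
13,25,0.78,0.84,0.81,0.71,0.20,0.31
14,49,0.66,0.88,0.75,1.00,0.08,0.15
15,31,0.88,0.90,0.89,0.73,0.35,0.48
16,12,0.71,1.00,0.83,1.00,0.50,0.67
17,17,0.45,1.00,0.62,1.00,0.47,0.64
18,9,0.53,0.89,0.67,0.67,0.22,0.33
19,8,0.89,1.00,0.94,0.50,0.13,0.20
20,15,0.64,0.93,0.76,1.00,0.13,0.24
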