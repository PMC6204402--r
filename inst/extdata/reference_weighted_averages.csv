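analyte,wa_me,wa_le,cc_printed,p_printed
delta9-Tetrahydrocannabinol,18.01,13.67,0.137,0.013
Cannabidiol,0.075,2.62,-0.944,0.097
Cannabigerol,0.68,0.76,-0.059,0.690
Cannabichromene,0.13,0.21,-0.248,0.120
Total terpenes,1.850,1.621,0.066,0.402
alpha-Pinene,0.160,0.092,0.270,0.265
Camphene,0.011,0.009,0.110,0.365
Sabinene,0.042,0.014,0.498,0.141
beta-Pinene,0.067,0.051,0.136,0.143
Myrcene,0.319,0.357,-0.057,0.703
alpha-Phellandrene,0.000,0.009,-1.000,0.046
3-Carene,0.000,0.006,-1.000,0.046
D-Limonene,0.211,0.150,0.168,0.237
Eucalyptol,0.000,0.005,-0.953,0.012
beta-Ocimene,0.007,0.042,-0.712,0.091
Terpinolene,0.019,0.134,-0.755,0.072
alpha-Terpinene,0.000,0.006,-0.959,0.067
gamma-Terpinene,0.000,0.005,-0.954,0.022
Sabinene hydrate,0.000,0.005,-0.843,0.018
Fenchone,0.013,0.013,0.030,0.834
Linalool,0.109,0.108,0.004,0.976
Fenchol,0.032,0.024,0.133,0.271
Borneol,0.020,0.023,-0.074,0.391
alpha-Terpineol,0.061,0.059,0.018,0.892
Geraniol,0.000,0.000,,
gamma-Terpineol,0.013,0.000,1.000,0.374
Nerol,0.000,0.000,,
beta-Caryophyllene,0.296,0.188,0.222,0.081
Caryophyllene oxide,0.010,0.006,0.260,0.311
Humulene,0.098,0.078,0.116,0.461
Valencene,0.003,0.000,1.000,0.332
trans-Nerolidol,0.444,0.146,0.503,0.018
Cedrol,0.000,0.000,,
Guaiol,0.000,0.069,-1.000,0.003
alpha-Bisabolol,0.077,0.039,0.335,0.108
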