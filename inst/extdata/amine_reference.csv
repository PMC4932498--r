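system,n_ads,label,total_amines,mean_amines,sem_amines,area_per_amine,consistent
G2-18C,19,19,152,21.7,1.6,0.35,TRUE
G2-18C,26,26,208,25.5,1.3,0.35,FALSE
G2-18C,24,24,192,13.6,1.2,0.32,TRUE
G2-18C,13,13,96,15.0,1.6,0.42,FALSE
G2-15C,19,19(1),152,19.9,1.6,0.35,TRUE
G2-15C,19,19(2),152,23.7,1.5,0.35,TRUE
G2-15C,15,15,120,20.7,1.6,0.40,TRUE
G2-15C,27,27,216,6.3,2.6,0.31,TRUE
G2-13C,12,12,96,15.8,2.0,0.40,TRUE
G2-13C,13,13,104,18.8,1.6,0.41,TRUE
G2-13C,15,15,120,16.1,2.0,0.37,TRUE
G2-13C,24,24,192,18.2,1.9,0.30,TRUE
G1-18C,28,28,112,22.9,1.8,0.39,TRUE
G1-18C,40,40,160,19.2,1.8,0.33,TRUE
G1-18C,58,58,232,24.4,1.9,0.29,TRUE
G0-18C,26,26,52,8.6,1.3,0.56,TRUE
G0-18C,131,131,262,30.7,1.9,0.29,TRUE
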