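system,n_ads,label,bound_sirna,micelle_radius,core_radius,tail_length,surface_area,core_volume,headgroup_volume,packing,consistent
G2-18C,13,13,TRUE,1.8,1.0,1.2,40.7,4.2,20.2,0.27,TRUE
G2-18C,18,18,FALSE,2.0,1.1,1.7,50.7,6.1,27.9,0.21,TRUE
G2-18C,19,19(1),TRUE,2.1,1.1,1.6,53.4,6.1,30.6,0.23,TRUE
G2-18C,19,19(2),FALSE,2.1,1.2,1.7,53.8,6.4,30.7,0.22,FALSE
G2-18C,24,24(1),FALSE,2.2,1.2,1.7,60.2,7.7,36.3,0.23,TRUE
G2-18C,24,24(2),TRUE,2.2,1.2,1.7,62.3,7.7,38.5,0.24,TRUE
G2-18C,26,26,TRUE,2.2,1.3,1.7,63.6,8.5,39.2,0.24,TRUE
G2-18C,32,32,FALSE,2.4,1.3,1.6,72.6,10.2,48.0,0.28,TRUE
G2-15C,15,15,TRUE,2.0,1.0,1.5,47.9,4.5,26.7,0.22,TRUE
G2-15C,18,18,FALSE,2.0,1.1,1.5,52.6,5.9,30.0,0.24,TRUE
G2-15C,19,19(1),TRUE,2.0,1.1,1.6,52.6,5.5,30.3,0.23,TRUE
G2-15C,19,19(2),TRUE,2.1,1.1,1.4,52.9,5.9,30.3,0.26,TRUE
G2-15C,20,20,FALSE,2.1,1.1,1.5,53.6,6.1,30.8,0.25,TRUE
G2-15C,26,26,FALSE,2.2,1.2,1.5,63.4,8.0,39.4,0.27,TRUE
G2-15C,27,27,TRUE,2.3,1.3,1.5,68.4,8.8,44.4,0.28,TRUE
G2-15C,31,31,FALSE,2.4,1.3,1.5,70.4,9.1,46.5,0.29,TRUE
G2-13C,12,12,TRUE,1.8,0.9,1.2,39.0,3.2,19.7,0.25,TRUE
G2-13C,13,13,TRUE,1.9,0.9,1.2,43.3,3.4,23.4,0.25,TRUE
G2-13C,15,15,TRUE,1.9,1.0,1.1,44.6,4.3,23.7,0.31,TRUE
G2-13C,19,19(1),FALSE,2.1,1.1,1.3,53.0,5.0,31.2,0.27,TRUE
G2-13C,19,19(2),FALSE,2.0,1.1,1.3,50.1,4.9,28.4,0.28,TRUE
G2-13C,22,22(1),FALSE,2.1,1.1,1.2,56.6,5.5,34.5,0.29,FALSE
G2-13C,22,22(2),FALSE,2.1,1.1,1.2,56.3,5.7,33.9,0.29,FALSE
G2-13C,24,24,TRUE,2.2,1.1,1.2,58.1,5.6,36.1,0.30,TRUE
G2-13C,29,29,FALSE,2.4,1.3,1.2,70.8,9.6,46.4,0.35,TRUE
G1-18C,28,28,TRUE,1.9,1.3,1.7,43.9,9.0,18.4,0.25,TRUE
G1-18C,40,40,TRUE,2.1,1.4,1.7,53.8,12.7,24.5,0.28,TRUE
G1-18C,49,49,FALSE,2.2,1.6,1.7,62.2,15.6,30.5,0.30,TRUE
G1-18C,58,58,TRUE,2.3,1.6,1.6,68.9,18.6,35.2,0.34,TRUE
G0-18C,18,18,FALSE,1.4,1.1,1.5,23.6,5.5,5.3,0.24,TRUE
G0-18C,26,26,TRUE,1.5,1.2,1.7,29.5,8.1,6.9,0.25,TRUE
G0-18C,131,131,TRUE,3.1,2.6,1.7,77.4,48.8,63.9,0.61,FALSE
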