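temp_C,source_ref,c_mid_M,K_D_per_M,sigma,c_ini_M,c_end_M,delta_F_kcal_mol,g_den_kcal_mol,delta_G0_kcal_mol,m_kcal_L_mol2
10,ref20,3.8,0.263,1.5e-3,2.7,5.3,-21.8,-0.379,9.55,2.512
15,ref20,4.0,0.25,1.8e-3,2.7,5.6,-22.7,-0.417,8.598,2.150
20,ref20,3.9,0.257,2.0e-3,2.6,5.5,-23.8,-0.436,8.598,2.210
25,ref20,3.8,0.263,2.5e-3,2.4,5.5,-26.1,-0.491,9.554,2.513
35,ref20,3.3,0.303,5.0e-3,1.75,5.1,-32.6,-0.654,8.598,2.605
10,ref17,3.8,0.26,1.0e-3,2.9,5.25,-20.1,-0.334,9.55,2.483
40,ref17,2.9,0.34,2.5e-3,1.9,4.1,-26.41,-0.493,8.36,2.842
60,ref17,1.1,0.9,3.0e-2,0.25,2.4,-65.5,-1.5,4.299,3.869
25,ref22,3.9,0.256,1.0e-3,2.8,5.15,-21.2,-0.361,10.03,2.568
10,ref21,4.1,0.243,2.0e-3,2.7,5.8,-22.55,-0.43,8.837,2.147391
30,ref15,3.9,0.258,1.0e-3,2.9,5.3,-21.7,-0.363,8.837,2.236
45,ref15,3.2,0.31,1.0e-2,1.3,5.3,-39.3,-0.888,4.777,2.236
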