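protein,n_residues,pH,denaturant,K_D_per_M,c_mid_M,sigma,c_ini_M,c_end_M,delta_c_M,g_den_kcal_mol,delta_F_kcal_mol,source_ref,temperature_K
BBL,41,7,GndHCl,0.33,3.03,3.0e-2,0.2,7.5,7.3,-2.14,-20.9,ref31,NA
ubiquitin WT,76,NA,GndHCl,0.34,2.94,7.0e-3,1.4,5,3.6,-0.753,-22.1,ref32,NA
ubiquitin L67S,76,NA,GndHCl,0.72,1.39,1.3e-2,0.5,2.7,2.2,-0.998,-28.4,ref32,NA
ubiquitin,76,2,GndHCl,0.395,2.53,8.0e-3,1.2,4.5,3.3,-0.782,-24.1,ref33,NA
ubiquitin,76,5.5,GndHCl,0.295,3.39,1.2e-2,1.3,6.3,5,-0.934,-26.4,ref33,NA
Apo lipoprotein A1,120,8,GndHCl,1,1.00,2.0e-2,0.3,2,1.7,-1.12,-49.7,ref34,NA
Apo lipoprotein A1,122,7.4,GndHCl,0.952,1.05,5.0e-3,0.6,1.7,1.1,-0.61,-32.8,ref35,NA
Apo lipoprotein A1,122,7.4,GndHCl,0.95,1.05,3.0e-2,0.3,2.3,2,-1.21,-55.9,ref36,NA
lysozyme,129,7,GndHCl,0.245,4.08,2.0e-3,2.8,5.8,3,-0.431,-24.6,ref16,NA
lysozyme,129,2,GndHCl,0.42,2.38,2.0e-2,0.8,4.6,3.8,-1.03,-49.6,ref37,NA
lysozyme,129,2.5,GndHCl,0.48,2.08,5.0e-3,1.1,3.2,2.1,-0.632,-31.1,ref37,NA
PMS-Ct,145,4,GndHCl,0.52,1.92,1.0e-3,1.1,2.5,1.4,-0.486,-22.7,ref38,NA
PMS-Ct,241,4,GndHCl,0.513,1.95,4.0e-3,1.1,2.7,1.6,-0.531,-45.3,ref38,NA
Ac-tyr-(ala-glu-ala-ala-lys-ala)5-phe-NH2,32,7,urea,0.25,4.00,8.0e-2,NA,NA,NA,NA,NA,ref6,NA
Ac-tyr-(ala-glu-ala-ala-lys-ala)8-phe-NH2,50,7,urea,0.2,5.00,1.0e-2,2.2,9.8,7.6,-0.884,-18.1,ref39,273
HPr protein,85,7,urea,0.215,4.65,8.0e-3,2,8,6,-0.793,-26.2,ref40,288
cytochrome c,106,5,urea,0.2,5.00,4.0e-3,2.9,7.7,4.8,-0.578,-25.1,ref3,NA
cytochrome c,106,7,urea,0.155,6.46,4.0e-3,3.6,9.5,5.9,-0.574,-22.5,ref3,NA
P22 1-domain,123,6,urea,0.3,3.33,9.0e-3,1.5,5.6,4.1,-0.753,-35.18,ref41,NA
lysozyme,129,2,urea,0.303,3.30,2.0e-2,2.2,6.4,4.2,-0.632,-47.9,ref37,NA
lysozyme,129,5.5,urea,0.15,6.67,2.0e-3,4.5,9.3,4.8,-0.43,-23.3,ref16,NA
anti-EGF-R mab,1600,7,urea,0.18,5.56,2.0e-2,2,8.3,6.3,-0.85,-407,ref3,NA
lysozyme,129,NA,SDS,230,0.00435,7.0e-2,0.001,0.012,0.011,-1.47,-77.7,ref18,298
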