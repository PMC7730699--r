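predicted_variable,r2_tr,rmsec,r2_cv,rmsecv,rpd,n_latent,n_obs
brightness,0.81,11.53,0.54,17.75,1.49,3,58
colour hue,0.85,11.14,0.70,15.87,1.84,3,58
homogeneity of surface,0.98,1.26,0.85,3.53,2.62,5,57
global odour intensity,0.90,3.15,0.49,7.08,1.41,5,59
sweet odour intensity,0.06,8.47,-0.25,9.75,0.90,1,63
sour odour intensity,0.59,2.49,0.14,3.61,1.09,3,57
floral odour intensity,0.95,0.70,0.75,1.62,2.03,5,55
hay odour intensity,0.96,1.28,0.84,2.75,2.48,5,56
global taste intensity,0.95,0.95,0.75,2.19,2.03,5,59
sweet taste intensity,0.61,5.11,0.20,7.33,1.13,3,61
sour taste intensity,0.96,5.11,0.67,14.20,1.75,5,55
floral taste intensity,0.96,0.30,0.84,0.62,2.50,4,61
hay taste intensity,0.77,2.08,0.20,3.91,1.13,4,61
off-taste intensity,0.95,4.83,0.74,10.64,2.00,5,58
aftertaste intensity,0.84,0.05,0.70,0.07,1.84,3,61
hardness,0.95,0.81,0.69,1.97,1.80,5,59
cohesiveness,0.95,6.17,0.68,15.39,1.79,5,58
mouthcoating,0.66,10.34,0.52,12.36,1.45,1,65
L_star,0.94,2.76,0.80,4.90,2.27,4,57
a_star,0.85,1.78,0.50,3.57,1.42,4,55
b_star,0.94,4.28,0.65,9.94,1.71,5,59
delta_C,0.78,6.92,0.59,9.43,1.58,3,61
delta_h,0.93,3.68,0.61,8.96,1.61,5,58
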