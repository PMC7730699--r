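predicted_variable,r2_tr,rmsec,r2_cv,rmsecv,rpd,n_latent,n_obs
brightness,0.68,14.91,0.22,22.88,1.14,5,46
colour hue,0.44,21.84,0.09,27.56,1.06,3,43
homogeneity of surface,0.73,4.87,0.54,6.26,1.49,4,50
global odour intensity,0.95,2.31,0.91,3.02,3.32,4,47
sweet odour intensity,0.76,4.39,0.58,5.83,1.55,4,45
sour odour intensity,0.78,1.92,0.57,2.67,1.54,5,49
floral odour intensity,0.66,1.97,0.16,3.05,1.11,5,47
hay odour intensity,0.54,4.75,0.16,6.37,1.11,4,45
global taste intensity,0.85,1.71,0.61,2.69,1.62,5,51
sweet taste intensity,0.88,2.96,0.77,4.11,2.10,4,44
sour taste intensity,0.65,14.47,0.43,18.40,1.34,4,51
floral taste intensity,0.90,0.46,0.85,0.57,2.61,4,44
hay taste intensity,0.98,0.55,0.97,0.69,5.94,4,44
off-taste intensity,0.88,6.96,0.68,10.88,1.80,5,49
aftertaste intensity,0.50,0.09,0.04,0.12,1.03,3,44
hardness,0.83,1.34,0.66,1.87,1.74,5,49
cohesiveness,0.59,16.76,0.21,22.94,1.14,4,45
mouthcoating,0.98,2.16,0.97,3.20,5.42,4,44
L_star,0.62,6.46,0.00,10.27,1.01,5,46
a_star,0.72,2.67,0.56,3.32,1.53,3,41
b_star,0.77,7.57,0.44,11.73,1.35,5,46
delta_C,0.72,7.64,0.46,10.47,1.37,3,45
delta_h,0.67,7.62,0.14,12.00,1.09,5,46
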