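predicted_variable,r2_tr,rmsec,r2_cv,rmsecv,rpd,n_latent,n_obs
brightness,0.99,2.14,0.96,4.61,5.06,5,70
colour hue,0.97,4.80,0.90,9.08,3.20,5,70
homogeneity of surface,0.99,0.77,0.98,1.40,6.67,5,70
global odour intensity,0.99,1.09,0.96,2.05,4.82,5,70
sweet odour intensity,0.98,1.21,0.94,2.13,3.99,5,70
sour odour intensity,0.98,0.66,0.94,1.07,4.09,5,70
floral odour intensity,0.97,0.58,0.91,1.02,3.34,5,70
hay odour intensity,0.97,1.15,0.91,2.03,3.42,5,70
global taste intensity,0.99,0.46,0.96,0.90,4.95,5,70
sweet taste intensity,0.99,0.87,0.96,1.69,5.12,5,70
sour taste intensity,0.99,2.45,0.97,4.41,5.65,5,70
floral taste intensity,0.99,0.14,0.97,0.24,6.25,4,70
hay taste intensity,0.99,0.47,0.96,0.88,4.92,5,70
off-taste intensity,0.98,2.96,0.93,5.62,3.73,5,70
aftertaste intensity,0.80,0.06,0.55,0.09,1.49,3,70
hardness,0.98,0.51,0.92,0.94,3.61,5,70
cohesiveness,0.97,4.87,0.89,8.72,2.98,5,70
mouthcoating,0.99,0.81,0.99,1.43,12.10,5,70
L_star,0.96,2.14,0.88,3.85,2.89,5,70
a_star,0.97,0.91,0.90,1.57,3.27,5,70
b_star,0.98,2.41,0.91,4.63,3.44,5,70
delta_C,0.98,1.99,0.92,3.91,3.64,5,70
delta_h,0.96,2.77,0.88,4.92,2.93,5,70
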