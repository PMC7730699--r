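predicted_variable,r2_tr,rmsec,r2_cv,rmsecv,rpd,n_latent,n_obs
brightness,0.66,15.38,0.44,19.44,1.39,2,15
colour hue,0.65,17.42,0.42,22.12,1.36,2,15
homogeneity of surface,0.69,5.23,0.00,9.22,1.03,2,15
global odour intensity,0.74,5.02,0.62,6.25,1.69,2,15
sweet odour intensity,0.68,4.86,0.53,5.85,1.52,2,15
sour odour intensity,0.56,2.88,0.37,3.46,1.31,2,15
floral odour intensity,0.72,1.79,0.27,2.84,1.21,2,15
hay odour intensity,0.87,2.46,0.26,5.52,1.21,2,15
global taste intensity,0.49,3.17,0.27,3.76,1.21,2,15
sweet taste intensity,0.92,2.39,0.89,2.81,3.16,2,15
sour taste intensity,0.48,18.20,-0.06,26.65,1.00,2,15
floral taste intensity,0.58,1.00,0.06,1.52,1.07,2,15
hay taste intensity,0.78,2.02,0.69,2.39,1.86,2,15
off-taste intensity,0.62,12.87,0.38,16.55,1.31,2,15
aftertaste intensity,0.67,0.08,0.49,0.09,1.45,2,15
hardness,0.54,2.31,0.32,2.81,1.25,2,15
cohesiveness,0.61,16.33,0.41,20.12,1.34,2,15
mouthcoating,0.97,2.91,0.87,5.66,2.88,2,15
L_star,0.68,6.38,0.50,8.25,1.46,2,15
a_star,0.81,2.26,0.62,3.15,1.69,2,15
b_star,0.76,7.84,0.61,9.92,1.65,2,15
delta_C,0.79,6.45,0.67,8.14,1.79,2,15
delta_h,0.62,9.04,0.41,11.14,1.35,2,15
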