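sample_1,sample_2,delta_E,delta_C,delta_h
lakeshore bulrush,sunflower,21.28,21.03,3.0
lakeshore bulrush,red clover,9.57,3.50,0.4
lakeshore bulrush,rapeseed,13.38,10.00,6.8
lakeshore bulrush,spiny plumeless thistle,38.90,21.46,34.7
sunflower,red clover,25.73,24.53,2.6
sunflower,rapeseed,17.12,11.03,9.8
sunflower,spiny plumeless thistle,53.56,42.49,31.7
red clover,rapeseed,21.46,13.50,7.2
red clover,spiny plumeless thistle,30.86,17.96,34.3
rapeseed,spiny plumeless thistle,52.01,31.46,41.5
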