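sample,L,a,b,L_sd,a_sd,b_sd,chroma_printed,hue_printed
lakeshore bulrush,59.6,6.0,44.2,0.4,0.1,0.9,44.6,82.3
sunflower,58.1,12.2,64.5,0.2,0.1,0.2,65.6,79.3
red clover,50.7,5.8,40.7,0.4,0.1,0.4,41.1,81.9
rapeseed,66.3,0.9,54.6,0.5,0.2,0.4,54.6,89.1
spiny plumeless thistle,33.4,15.6,17.1,0.3,0.2,0.3,23.1,47.6
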