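attribute,sample,mean,sd
brightness,lakeshore bulrush,45.5,3.9
brightness,sunflower,29.6,3.7
brightness,red clover,68.9,2.1
brightness,rapeseed,11.5,2.0
brightness,spiny plumeless thistle,84.3,3.5
colour hue,lakeshore bulrush,40.9,2.7
colour hue,sunflower,23.9,2.4
colour hue,red clover,61.7,2.0
colour hue,rapeseed,11.4,2.0
colour hue,spiny plumeless thistle,94.1,1.9
homogeneity of surface,lakeshore bulrush,62.9,3.0
homogeneity of surface,sunflower,64.5,5.1
homogeneity of surface,red clover,80.8,1.7
homogeneity of surface,rapeseed,85.6,3.5
homogeneity of surface,spiny plumeless thistle,81.3,1.9
global odour intensity,lakeshore bulrush,85.6,3.4
global odour intensity,sunflower,63.8,2.9
global odour intensity,red clover,70.0,3.4
global odour intensity,rapeseed,88.0,3.2
global odour intensity,spiny plumeless thistle,86.5,3.4
sweet odour intensity,lakeshore bulrush,63.0,3.0
sweet odour intensity,sunflower,67.0,2.8
sweet odour intensity,red clover,56.7,2.7
sweet odour intensity,rapeseed,71.3,2.6
sweet odour intensity,spiny plumeless thistle,82.4,2.2
sour odour intensity,lakeshore bulrush,17.3,3.2
sour odour intensity,sunflower,5.5,1.7
sour odour intensity,red clover,6.0,2.1
sour odour intensity,rapeseed,10.4,1.1
sour odour intensity,spiny plumeless thistle,7.1,2.5
floral odour intensity,lakeshore bulrush,11.8,2.4
floral odour intensity,sunflower,6.3,2.3
floral odour intensity,red clover,3.2,2.8
floral odour intensity,rapeseed,8.7,1.8
floral odour intensity,spiny plumeless thistle,2.8,2.7
hay odour intensity,lakeshore bulrush,20.3,3.7
hay odour intensity,sunflower,11.7,2.9
hay odour intensity,red clover,2.8,2.5
hay odour intensity,rapeseed,14.8,2.5
hay odour intensity,spiny plumeless thistle,2.4,2.0
global taste intensity,lakeshore bulrush,87.8,3.9
global taste intensity,sunflower,92.0,2.8
global taste intensity,red clover,83.3,4.1
global taste intensity,rapeseed,81.8,3.8
global taste intensity,spiny plumeless thistle,79.8,2.8
sweet taste intensity,lakeshore bulrush,86.2,4.8
sweet taste intensity,sunflower,64.4,3.5
sweet taste intensity,red clover,72.8,5.0
sweet taste intensity,rapeseed,68.4,2.8
sweet taste intensity,spiny plumeless thistle,84.1,3.9
sour taste intensity,lakeshore bulrush,7.4,3.5
sour taste intensity,sunflower,14.4,3.6
sour taste intensity,red clover,47.7,4.1
sour taste intensity,rapeseed,69.1,2.4
sour taste intensity,spiny plumeless thistle,63.4,5.5
floral taste intensity,lakeshore bulrush,5.5,2.8
floral taste intensity,sunflower,5.5,3.0
floral taste intensity,red clover,8.3,2.3
floral taste intensity,rapeseed,9.0,1.8
floral taste intensity,spiny plumeless thistle,8.3,3.3
hay taste intensity,lakeshore bulrush,4.4,1.6
hay taste intensity,sunflower,15.5,3.0
hay taste intensity,red clover,7.6,2.5
hay taste intensity,rapeseed,4.0,2.6
hay taste intensity,spiny plumeless thistle,4.8,0.6
off-taste intensity,lakeshore bulrush,42.3,5.5
off-taste intensity,sunflower,64.6,5.6
off-taste intensity,red clover,32.8,4.6
off-taste intensity,rapeseed,32.5,5.8
off-taste intensity,spiny plumeless thistle,0.0,0.0
aftertaste intensity,lakeshore bulrush,0.1,0.4
aftertaste intensity,sunflower,0.0,0.0
aftertaste intensity,red clover,0.0,0.4
aftertaste intensity,rapeseed,0.0,0.0
aftertaste intensity,spiny plumeless thistle,0.4,1.3
hardness,lakeshore bulrush,10.5,1.0
hardness,sunflower,8.4,2.3
hardness,red clover,11.0,1.8
hardness,rapeseed,13.4,2.0
hardness,spiny plumeless thistle,18.4,3.6
cohesiveness,lakeshore bulrush,10.4,0.8
cohesiveness,sunflower,8.9,3.3
cohesiveness,red clover,12.1,2.3
cohesiveness,rapeseed,5.9,2.0
cohesiveness,spiny plumeless thistle,74.6,5.9
mouthcoating,lakeshore bulrush,76.8,3.4
mouthcoating,sunflower,86.8,3.6
mouthcoating,red clover,35.9,4.8
mouthcoating,rapeseed,63.8,2.5
mouthcoating,spiny plumeless thistle,71.0,4.1
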