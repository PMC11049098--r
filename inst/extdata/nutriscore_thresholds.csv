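component,scale,threshold,points
energy,food,335,1
energy,food,670,2
energy,food,1005,3
energy,food,1340,4
energy,food,1675,5
energy,food,2010,6
energy,food,2345,7
energy,food,2680,8
energy,food,3015,9
energy,food,3350,10
energy,beverage,0,1
energy,beverage,30,2
energy,beverage,60,3
energy,beverage,90,4
energy,beverage,120,5
energy,beverage,150,6
energy,beverage,180,7
energy,beverage,210,8
energy,beverage,240,9
energy,beverage,270,10
sugars,food,4.5,1
sugars,food,9,2
sugars,food,13.5,3
sugars,food,18,4
sugars,food,22.5,5
sugars,food,27,6
sugars,food,31,7
sugars,food,36,8
sugars,food,40,9
sugars,food,45,10
sugars,beverage,0,1
sugars,beverage,1.5,2
sugars,beverage,3,3
sugars,beverage,4.5,4
sugars,beverage,6,5
sugars,beverage,7.5,6
sugars,beverage,9,7
sugars,beverage,10.5,8
sugars,beverage,12,9
sugars,beverage,13.5,10
sfa,food,1,1
sfa,food,2,2
sfa,food,3,3
sfa,food,4,4
sfa,food,5,5
sfa,food,6,6
sfa,food,7,7
sfa,food,8,8
sfa,food,9,9
sfa,food,10,10
sodium,food,90,1
sodium,food,180,2
sodium,food,270,3
sodium,food,360,4
sodium,food,450,5
sodium,food,540,6
sodium,food,630,7
sodium,food,720,8
sodium,food,810,9
sodium,food,900,10
protein,food,1.6,1
protein,food,3.2,2
protein,food,4.8,3
protein,food,6.4,4
protein,food,8,5
fiber,food,0.9,1
fiber,food,1.9,2
fiber,food,2.8,3
fiber,food,3.7,4
fiber,food,4.7,5
fv,food,40,1
fv,food,60,2
fv,food,80,5
fv,beverage,40,2
fv,beverage,60,4
fv,beverage,80,10
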