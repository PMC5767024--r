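ID,SAH,DM,Creatinine,Urea,Microalbuminuria,Potassium,Weight,Age,Gender,GFR
2,X,X,0.54,25.2,0.6,4.1,80,60,F,139.9
3,X,,0.81,33,77.5,3.9,61,79,M,63.8
4,X,X,0.6,33.4,5,4.2,87,49,F,155.7
5,X,X,2.06,65.1,26.9,4.4,101,74,M,36.6
6,X,,2.34,128,,4.4,67.4,50,M,36.6
7,X,X,1.1,30.5,45,4.8,70,55,M,75.1
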