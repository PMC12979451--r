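variable,group,n,mean,sd,test
age,MDD-CM,84,25.45,5.61,anova
age,MDD-nCM,46,26.76,8.00,anova
age,HC-CM,32,26.59,7.26,anova
age,HC-nCM,90,27.12,7.65,anova
education,MDD-CM,84,14.83,2.24,anova
education,MDD-nCM,46,15.00,2.70,anova
education,HC-CM,32,15.47,2.59,anova
education,HC-nCM,90,15.31,2.26,anova
HAMD,MDD-CM,84,31.92,9.41,t
HAMD,MDD-nCM,46,27.67,9.87,t
HAMA,MDD-CM,84,21.45,7.77,t
HAMA,MDD-nCM,46,18.11,7.43,t
CTQ,MDD-CM,84,55.25,13.46,anova
CTQ,MDD-nCM,46,36.98,6.61,anova
CTQ,HC-CM,32,41.81,8.84,anova
CTQ,HC-nCM,90,30.38,4.06,anova
EA,MDD-CM,84,11.57,4.69,anova
EA,MDD-nCM,46,7.65,1.99,anova
EA,HC-CM,32,8.25,3.20,anova
EA,HC-nCM,90,5.92,1.40,anova
PA,MDD-CM,84,7.81,3.68,anova
PA,MDD-nCM,46,5.54,0.81,anova
PA,HC-CM,32,6.78,2.94,anova
PA,HC-nCM,90,5.29,0.55,anova
SA,MDD-CM,84,6.68,3.20,anova
SA,MDD-nCM,46,5.09,0.35,anova
SA,HC-CM,32,5.94,2.42,anova
SA,HC-nCM,90,5.10,0.37,anova
EN,MDD-CM,84,16.69,4.19,anova
EN,MDD-nCM,46,10.41,2.48,anova
EN,HC-CM,32,11.41,4.83,anova
EN,HC-nCM,90,8.06,2.55,anova
PN,MDD-CM,84,11.45,3.64,anova
PN,MDD-nCM,46,7.11,1.62,anova
PN,HC-CM,32,9.44,2.64,anova
PN,HC-nCM,90,6.01,1.26,anova
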