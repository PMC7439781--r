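id,group,age,sex,height,weight,sbp,dbp,aad,z_score,viscosity
P1,nondilated,6.9,F,118,19.0,108,62,17.59,0.64,4.28
P2,nondilated,21.8,M,163,50.0,130,85,27.18,1.73,10.01
P3,nondilated,8.7,M,126,22.0,107,61,20.69,1.76,4.08
P4,nondilated,8.4,M,119,20.0,98,64,20.16,1.86,6.73
P5,nondilated,6.1,M,110,18.0,105,59,20.12,2.34,6.48
P6,nondilated,21.3,F,150,45.0,105,56,30.32,3.13,6.07
P7,nondilated,15.2,M,162,40.0,112,62,25.29,3.92,6.08
P8,nondilated,15.1,M,170,52.0,95,58,30.32,4.11,4.14
P9,nondilated,20.3,M,171,65.0,140,96,35.43,4.12,7.18
P10,nondilated,12.0,M,138,31.5,88,57,29.76,4.15,2.78
P11,dilated,7.6,F,129,20.0,79,50,20.60,5.81,3.82
P12,dilated,7.8,M,113,16.0,109,74,25.70,5.88,7.22
P13,dilated,10.4,F,125,23.0,105,60,30.89,7.03,7.27
P14,dilated,8.8,M,115,20.0,105,70,27.79,7.35,8.83
P15,dilated,19.9,M,166,46.0,133,77,40.17,7.45,8.59
P16,dilated,13.0,M,157,37.0,118,54,35.96,7.82,3.69
P17,dilated,13.2,M,152,28.0,129,69,37.07,8.66,8.30
P18,dilated,19.3,M,170,45.0,99,63,39.26,9.72,7.64
P19,dilated,8.6,F,120,15.0,90,60,28.71,11.36,4.74
P20,dilated,6.9,F,106,15.0,99,40,29.17,11.90,4.10
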