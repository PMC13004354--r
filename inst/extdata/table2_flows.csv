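system,pressure_psi,flow_ul_s
model3219,6,0.82
model3219,8,2.45
model3219,10,4.09
model3219,12,5.73
model3219,14,7.36
model3219,16,9.00
model3219,18,10.64
model3219,20,12.27
model3255,6,1.91
model3255,8,5.72
model3255,10,9.53
model3255,12,13.34
model3255,14,17.16
model3255,16,20.97
model3255,18,24.78
model3255,20,28.60
model3263,6,0.17
model3263,8,0.51
model3263,10,0.86
model3263,12,1.20
model3263,14,1.54
model3263,16,1.89
model3263,18,2.23
model3263,20,2.57
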