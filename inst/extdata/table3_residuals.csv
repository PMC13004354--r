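pressure_psi,condition,mean_s,sd_s,n
6,BC,27.7,0.47,3
8,BC,34.7,0.5,3
10,BC,39,1.41,3
12,BC,42.3,0.47,3
14,BC,45,0.8,3
16,BC,43,0.82,3
18,BC,45.7,0.47,3
20,BC,47.3,0.5,3
8,MP1,35.5,1.1,4
14,MP1,41.7,0.7,4
20,MP1,44.5,1.1,4
8,MP2,39.7,1,4
14,MP2,44.7,0.8,4
20,MP2,47.5,1.1,4
8,MP3,58.5,0.5,4
14,MP3,64.3,1.5,4
20,MP3,74.3,1,4
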