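case,lobe,ct_lr,ct_ap,ct_si,sim_lr,sim_ap,sim_si,printed_err_lr,printed_err_ap,printed_err_si
1,RL,3.38,8.59,38.70,3.40,8.62,38.00,0.5,0.3,1.8
2,RL,-14.80,0.48,27.39,-14.50,0.50,28.01,2.0,4.1,2.2
3,RL,-5.93,15.10,27.90,-5.91,15.55,27.60,0.3,2.9,1.0
4,LL,0.42,9.50,35.89,0.40,9.35,34.95,4.7,1.7,2.6
5,LL,13.74,-1.27,23.71,13.57,1.22,23.60,1.2,3.9,0.4
6,RL,8.84,11.65,31.59,8.74,12.01,31.52,1.1,3.0,0.2
7,LL,6.35,16.25,39.82,6.42,16.55,39.99,1.1,1.8,0.4
8,LL,-5.89,3.52,35.23,-5.59,3.42,34.97,5.0,2.8,0.7
9,LL,-4.66,10.36,78.59,-4.52,9.98,78.05,3.0,3.6,0.6
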