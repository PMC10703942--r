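case,sex,inspiration_L,ct_expiration_L,fem_expiration_L
1,M,5.33,3.10,3.14
2,F,3.57,1.64,1.78
3,M,5.44,2.72,2.87
4,M,5.51,1.95,2.13
5,M,4.92,2.48,2.30
6,M,4.92,3.29,3.10
7,F,3.99,2.22,2.25
8,M,5.53,1.95,2.12
9,M,4.25,1.70,1.83
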