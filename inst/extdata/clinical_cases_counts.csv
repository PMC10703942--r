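case,lobe,n_landmarks,n_elements,minutes
1,RL,29,246783,20
2,RL,28,1045295,60
3,RL,31,868267,51
4,LL,30,403689,28
5,LL,28,596615,31
6,RL,33,499492,30
7,LL,29,511069,30
8,LL,28,741115,42
9,LL,22,615616,38
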