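combo,primer,n_markers,error_rate,n_susceptible,n_polymorphic
1,EcoRI+ACC/HpaII-MspI+TAC,29,0.029,16,9
2,EcoRI+ACC/HpaII-MspI+TAG,22,0.000,21,16
3,EcoRI+AGC/HpaII-MspI+TCC,25,0.024,13,13
4,EcoRI+AGC/HpaII-MspI+TCT,28,0.033,10,3
5,EcoRI+AGC/HpaII-MspI+TCG,20,0.038,9,4
6,EcoRI+AGC/HpaII-MspI+TAA,51,0.044,10,10
7,EcoRI+ACT/HpaII-MspI+TAG,41,0.028,15,10
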