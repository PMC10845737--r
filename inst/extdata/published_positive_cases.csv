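stratum,n_positive_cases,n_referred,n_misclassified
Center A,28,1,0
Center B,20,0,0
Center C,37,0,0
Center D,40,3,1
Hamamatsu,30,2,0
3D Histech,22,2,1
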