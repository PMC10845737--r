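stratum,n_sets,error_type,n,technical,missing_sens_spec,new_abnormal,unknown
Center A,675,false_positive,2,0,0,2,0
Center A,675,false_negative,46,28,17,0,1
Center B,417,false_positive,5,0,5,0,0
Center B,417,false_negative,41,25,16,0,0
Center C,465,false_positive,3,0,3,0,0
Center C,465,false_negative,25,22,2,0,1
Center D,667,false_positive,23,0,20,3,0
Center D,667,false_negative,3,0,3,0,0
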