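stratum,n_sets,error_type,n,technical,missing_sens_spec,new_abnormal,unknown
Hamamatsu,348,false_positive,3,2,1,0,0
Hamamatsu,348,false_negative,8,0,7,1,0
3D Histech,447,false_positive,40,7,10,0,23
3D Histech,447,false_negative,4,0,4,0,0
Philips,667,false_positive,23,0,20,3,0
Philips,667,false_negative,3,0,3,0,0
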