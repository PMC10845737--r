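cohort,n_cases,n_hscr,n_non_hscr,n_correct,n_incorrect,n_referrals
Center A,49,21,28,49,0,1
Center B,29,9,20,29,0,0
Center C,49,12,37,49,0,0
Center D,59,20,39,58,1,3
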