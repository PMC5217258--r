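predictor,exposed_events,exposed_nonevents,unexposed_events,unexposed_nonevents,published_or
residential_care,277,471,2788,12917,2.72
aki_stage1,528,1190,2154,11676,2.41
aki_stage2,233,341,2154,11676,3.70
aki_stage3,150,181,2154,11676,4.49
cardiac_failure,317,592,2748,12796,2.49
dementia,96,163,2969,13225,2.62
emergency,2326,7760,739,5628,2.28
cancer,410,973,2655,12415,1.97
rural,735,3720,2330,9668,0.82
nonrecovery,520,1167,2545,12221,2.14
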