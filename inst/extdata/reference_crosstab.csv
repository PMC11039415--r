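severity,ratio_ge_0.7,ratio_lt_0.7,missing
normal,3693,826,16
mild,974,2418,5
moderate,758,2897,8
moderately_severe,427,2837,6
severe,288,5241,18
very_severe,61,3247,9
missing,1044,149,0
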