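group,weighted_n
unemployed,219652
underemployed_nonprecarious,235548
underemployed_precarious,1214348
employed_precarious,1762996
employed_nonprecarious,1384386
printed_total,4816930
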