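quantity,p_start,p_end,start_period,end_period
underemployment_share,26.7,33.7,2005-2006,2019
health_employment_share,68.6,61.4,2005-2006,2019
private_non_or_low_precarious,60.8,47.1,2005-2006,2019
public_non_or_low_precarious,89.9,79.6,2005-2006,2019
university_nonprecarious_employment,32.7,40.3,no_university,university
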