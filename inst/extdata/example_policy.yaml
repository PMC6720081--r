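# Illustrative dual time-interval policy (days); a real review
# must pre-specify its own thresholds.
diagnostic_inclusion_max_days: 30
diagnostic_low_rob_max_days: 14
prognostic_inclusion_min_days: 365
prognostic_low_rob_min_days: 365
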