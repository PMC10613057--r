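working_days_per_year: 264
nonclinical_time_share: 0.30
exchange_rate_kes_per_usd: 101.99
digits_per_capita: 1
digits_totals: 0
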