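exchange_rate,gdp_per_capita,health_expenditure_share,cost_unit
48.14,9912,0.091,USD
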