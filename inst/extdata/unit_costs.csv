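item,unit_cost_gbp,price_year,index_type
mammogram,115.25,2023,NHSCII
mammogram_low,33,2023,NHSCII
mammogram_high,272,2023,NHSCII
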