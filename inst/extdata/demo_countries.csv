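country_id,currency_label,anchor_value,large_multiplier,gini,log_gdp_pc,inflation_rate
US,US dollar (synthetic demo),500,10,0.41,11.05,4.7
BR,Brazilian real (synthetic demo),1300,10,0.53,8.96,8.3
JP,Japanese yen (synthetic demo),50000,10,0.33,10.44,0.2
NG,Nigerian naira (synthetic demo),43000,10,0.35,7.68,17.0
DE,euro (synthetic demo),950,10,0.31,10.73,3.1
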