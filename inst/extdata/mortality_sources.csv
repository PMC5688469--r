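"country_id","source_label","nmr","mmr"
"C01","IGME",44.65,631.2
"C01","IHME",37.96,757.4
"C01","DHS",49.12,568
"C02","IGME",57.95,755.5
"C02","IHME",49.25,906.7
"C02","DHS",63.74,680
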