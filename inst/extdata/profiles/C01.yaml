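country_id: C01
baseline_year: 2010
horizon_year: 2015
tfr0: 4.211657874286175
women_reproductive_age: 1375358.0
nmr0: 44.654988589463755
mmr0: 631.165550276637077
neonatal_cause_fractions:
  prematurity: 0.140676902212335
  birth_asphyxia: 0.093740560687608
  neonatal_sepsis: 0.012615355569794
  neonatal_pneumonia: 0.752967181530264
maternal_cause_fractions:
  haemorrhage: 0.183475770758252
  hypertensive_disorders: 0.093155920195952
  maternal_sepsis: 0.008131843204521
  obstructed_labour: 0.715236465841274
baseline_coverage:
  fp_modern_methods: 0.548559352196753
  intv_01: 0.409320948086679
  intv_02: 0.280424652877264
  intv_03: 0.133239492680877
  intv_04: 0.364185007661581
  intv_05: 0.598379347729497
  intv_06: 0.232106644101441
  intv_07: 0.277848117775284
  intv_08: 0.258723382512107
  intv_09: 0.212210645689629
  intv_10: 0.442743944842368
  intv_11: 0.195611115917563
  intv_12: 0.575628395215608
cp0: 0.076513565704227
contraceptive_effectiveness: 0.9
mortality_source: IGME
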