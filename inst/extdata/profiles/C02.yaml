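country_id: C02
baseline_year: 2010
horizon_year: 2015
tfr0: 3.244666884886101
women_reproductive_age: 1668133.0
nmr0: 57.945978397037834
mmr0: 755.54670374840498
neonatal_cause_fractions:
  prematurity: 0.040973675971125
  birth_asphyxia: 0.682577513105029
  neonatal_sepsis: 0.01122046727372
  neonatal_pneumonia: 0.091556725935484
  congenital: 0.034382379866677
  neonatal_tetanus: 0.139289237847964
maternal_cause_fractions:
  haemorrhage: 0.338499322615664
  hypertensive_disorders: 0.15409576989426
  maternal_sepsis: 0.420159681524016
  obstructed_labour: 0.077668563491856
  abortion_complications: 0.009576662474205
baseline_coverage:
  fp_modern_methods: 0.540477990196086
  intv_01: 0.562211026926525
  intv_02: 0.281745713111013
  intv_03: 0.259789070836268
  intv_04: 0.119242969807237
  intv_05: 0.284290573350154
  intv_06: 0.423523990460671
  intv_07: 0.312704856763594
  intv_08: 0.272342975623906
  intv_09: 0.499997238069773
  intv_10: 0.138516205037013
  intv_11: 0.257486767042428
  intv_12: 0.588630941603333
cp0: 0.443107559345663
contraceptive_effectiveness: 0.9
mortality_source: IGME
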