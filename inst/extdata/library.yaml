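interventions:
- intervention_id: fp_modern_methods
  name: Modern contraceptive methods
  period: pre-pregnancy
  category: preventive
  is_family_planning: yes
  effects: []
- intervention_id: intv_01
  name: Intervention 01
  period: pre-pregnancy
  category: preventive
  is_family_planning: no
  effects:
  - target_group: neonatal
    cause: birth_asphyxia
    effectiveness: 0.549832108966075
    affected_fraction: 0.51256557519082
- intervention_id: intv_02
  name: Intervention 02
  period: pregnancy
  category: preventive
  is_family_planning: no
  effects:
  - target_group: maternal
    cause: haemorrhage
    effectiveness: 0.672679345891811
    affected_fraction: 0.615562523482367
- intervention_id: intv_03
  name: Intervention 03
  period: childbirth
  category: preventive
  is_family_planning: no
  effects:
  - target_group: maternal
    cause: maternal_sepsis
    effectiveness: 0.051077852398157
    affected_fraction: 0.658912244951352
  - target_group: maternal
    cause: haemorrhage
    effectiveness: 0.359094919962808
    affected_fraction: 0.616281346650794
- intervention_id: intv_04
  name: Intervention 04
  period: postnatal
  category: preventive
  is_family_planning: no
  effects:
  - target_group: maternal
    cause: hypertensive_disorders
    effectiveness: 0.419604857335798
    affected_fraction: 0.570040427846834
  - target_group: neonatal
    cause: prematurity
    effectiveness: 0.708068671892397
    affected_fraction: 0.508078604820184
- intervention_id: intv_05
  name: Intervention 05
  period: pre-pregnancy
  category: curative
  is_family_planning: no
  effects:
  - target_group: neonatal
    cause: neonatal_sepsis
    effectiveness: 0.479480097512715
    affected_fraction: 0.877411637455225
  - target_group: maternal
    cause: hypertensive_disorders
    effectiveness: 0.441137576615438
    affected_fraction: 0.720068388269283
- intervention_id: intv_06
  name: Intervention 06
  period: pregnancy
  category: curative
  is_family_planning: no
  effects:
  - target_group: neonatal
    cause: prematurity
    effectiveness: 0.315109667484648
    affected_fraction: 0.759612143738195
  - target_group: neonatal
    cause: prematurity
    effectiveness: 0.619260351080447
    affected_fraction: 0.979134582914412
- intervention_id: intv_07
  name: Intervention 07
  period: childbirth
  category: curative
  is_family_planning: no
  effects:
  - target_group: maternal
    cause: maternal_sepsis
    effectiveness: 0.716578459646553
    affected_fraction: 0.522948161931708
- intervention_id: intv_08
  name: Intervention 08
  period: postnatal
  category: curative
  is_family_planning: no
  effects:
  - target_group: maternal
    cause: haemorrhage
    effectiveness: 0.856015401356854
    affected_fraction: 0.783037886023521
  - target_group: neonatal
    cause: neonatal_sepsis
    effectiveness: 0.46858549087774
    affected_fraction: 0.786189229576848
- intervention_id: intv_09
  name: Intervention 09
  period: pre-pregnancy
  category: preventive
  is_family_planning: no
  effects:
  - target_group: neonatal
    cause: neonatal_sepsis
    effectiveness: 0.701216881372966
    affected_fraction: 0.92892897175625
- intervention_id: intv_10
  name: Intervention 10
  period: pregnancy
  category: preventive
  is_family_planning: no
  effects:
  - target_group: neonatal
    cause: neonatal_sepsis
    effectiveness: 0.537625943613239
    affected_fraction: 0.602356299175881
- intervention_id: intv_11
  name: Intervention 11
  period: childbirth
  category: preventive
  is_family_planning: no
  effects:
  - target_group: maternal
    cause: haemorrhage
    effectiveness: 0.753543613408692
    affected_fraction: 0.981067982385866
  - target_group: maternal
    cause: haemorrhage
    effectiveness: 0.608422551536933
    affected_fraction: 0.963713632780127
- intervention_id: intv_12
  name: Intervention 12
  period: postnatal
  category: preventive
  is_family_planning: no
  effects:
  - target_group: neonatal
    cause: prematurity
    effectiveness: 0.735531249456108
    affected_fraction: 0.642638725345023
  - target_group: neonatal
    cause: birth_asphyxia
    effectiveness: 0.759163817157969
    affected_fraction: 0.682249995530583
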