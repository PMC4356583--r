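format: ihtsa cohort column dictionary
version: 1.0
csv:
  encoding: UTF-8
  separator: ','
  decimal: '.'
  missing: ''
columns:
  recipient_age:
    kind: continuous
    unit: years
    role: recipient
    maskable: yes
  recipient_sex:
    kind: categorical
    unit: ''
    role: recipient
    maskable: yes
    levels:
    - female
    - male
  recipient_height:
    kind: continuous
    unit: cm
    role: recipient
    maskable: yes
  recipient_weight:
    kind: continuous
    unit: kg
    role: recipient
    maskable: yes
  diagnosis:
    kind: categorical
    unit: ''
    role: recipient
    maskable: yes
    levels:
    - ischemic_cm
    - non_ischemic_cm
    - congenital
    - graft_failure
    - valvular
    - other
  diabetes:
    kind: indicator
    unit: ''
    role: recipient
    maskable: yes
  hypertension:
    kind: indicator
    unit: ''
    role: recipient
    maskable: yes
  infection_2wk:
    kind: indicator
    unit: ''
    role: recipient
    maskable: yes
  antiarrhythmics:
    kind: indicator
    unit: ''
    role: recipient
    maskable: yes
  amiodarone:
    kind: indicator
    unit: ''
    role: recipient
    maskable: yes
  prior_transfusion:
    kind: indicator
    unit: ''
    role: recipient
    maskable: yes
  prior_transplant:
    kind: indicator
    unit: ''
    role: recipient
    maskable: yes
  prior_cardiac_surgery:
    kind: indicator
    unit: ''
    role: recipient
    maskable: yes
  icu:
    kind: indicator
    unit: ''
    role: recipient
    maskable: yes
  ventilator:
    kind: indicator
    unit: ''
    role: recipient
    maskable: yes
  ecmo:
    kind: indicator
    unit: ''
    role: recipient
    maskable: yes
  vad:
    kind: indicator
    unit: ''
    role: recipient
    maskable: yes
  era:
    kind: categorical
    unit: ''
    role: recipient
    maskable: no
    levels:
    - 1991-1995
    - 1996-2000
    - 2001-2005
    - 2006-2010
  spp:
    kind: continuous
    unit: mmHg
    role: recipient
    maskable: yes
  pvr:
    kind: continuous
    unit: Wood units
    role: recipient
    maskable: yes
  creatinine:
    kind: continuous
    unit: umol/l
    role: recipient
    maskable: yes
  bilirubin:
    kind: continuous
    unit: mg/dl
    role: recipient
    maskable: yes
  pra_gt10:
    kind: indicator
    unit: ''
    role: recipient
    maskable: yes
  hladr_mismatch:
    kind: categorical
    unit: ''
    role: recipient
    maskable: yes
    levels:
    - '0'
    - '1'
    - '2'
  recipient_bg:
    kind: categorical
    unit: ''
    role: recipient
    maskable: yes
    levels:
    - A
    - AB
    - B
    - O
  donor_age:
    kind: continuous
    unit: years
    role: donor
    maskable: yes
  donor_sex:
    kind: categorical
    unit: ''
    role: donor
    maskable: yes
    levels:
    - female
    - male
  donor_weight:
    kind: continuous
    unit: kg
    role: donor
    maskable: yes
  ischemia_min:
    kind: continuous
    unit: minutes
    role: donor
    maskable: yes
  codd_head_trauma:
    kind: indicator
    unit: ''
    role: donor
    maskable: yes
  codd_cva:
    kind: indicator
    unit: ''
    role: donor
    maskable: yes
  donor_bg:
    kind: categorical
    unit: ''
    role: donor
    maskable: yes
    levels:
    - A
    - AB
    - B
    - O
  followup_years:
    kind: continuous
    unit: years
    role: outcome
    maskable: no
  death:
    kind: indicator
    unit: ''
    role: outcome
    maskable: no
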