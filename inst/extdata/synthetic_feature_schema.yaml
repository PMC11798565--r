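features:
- name: age_z
  category: demographic
  type: continuous
  mean:
    healthy: 0.0
    mdd: 0.1
    bd: 0.0
    sz: -0.2
    other: 0.0
  sd: 1.0
- name: bmi_z
  category: health_background
  type: continuous
  mean:
    healthy: 0.0
    mdd: 0.0
    bd: 0.0
    sz: 0.3
    other: 0.0
  sd: 1.0
- name: sleep_hours_z
  category: psychiatric
  type: continuous
  mean:
    healthy: 0.0
    mdd: -0.35
    bd: -0.3
    sz: -0.45
    other: -0.15
  sd: 1.0
- name: bedtime_shift_z
  category: psychiatric
  type: continuous
  mean:
    healthy: 0.0
    mdd: 0.3
    bd: 0.35
    sz: 0.45
    other: 0.15
  sd: 1.0
- name: perceived_stress_z
  category: psychiatric
  type: continuous
  mean:
    healthy: 0.0
    mdd: 0.45
    bd: 0.4
    sz: 0.5
    other: 0.25
  sd: 1.0
- name: depressive_symptoms_z
  category: psychiatric
  type: continuous
  mean:
    healthy: 0.0
    mdd: 0.6
    bd: 0.45
    sz: 0.5
    other: 0.25
  sd: 1.0
- name: ikigai_z
  category: psychiatric
  type: continuous
  mean:
    healthy: 0.0
    mdd: -0.4
    bd: -0.3
    sz: -0.5
    other: -0.2
  sd: 1.0
- name: internet_hours_z
  category: psychiatric
  type: continuous
  mean:
    healthy: 0.0
    mdd: 0.15
    bd: 0.2
    sz: 0.3
    other: 0.1
  sd: 1.0
- name: functional_restriction_z
  category: health_background
  type: continuous
  mean:
    healthy: 0.0
    mdd: 0.3
    bd: 0.3
    sz: 0.45
    other: 0.15
  sd: 1.0
- name: self_rated_health_z
  category: health_background
  type: continuous
  mean:
    healthy: 0.0
    mdd: -0.35
    bd: -0.25
    sz: -0.45
    other: -0.15
  sd: 1.0
- name: sleep_medication_freq
  category: psychiatric
  type: ordinal
  levels:
  - 0
  - 1
  - 2
  - 3
  prob:
    healthy:
    - 0.8
    - 0.12
    - 0.05
    - 0.03
    mdd:
    - 0.5
    - 0.2
    - 0.18
    - 0.12
    bd:
    - 0.5
    - 0.2
    - 0.17
    - 0.13
    sz:
    - 0.45
    - 0.2
    - 0.2
    - 0.15
    other:
    - 0.7
    - 0.15
    - 0.1
    - 0.05
- name: smoking
  category: demographic
  type: ordinal
  levels:
  - 0
  - 1
  - 2
  prob:
    healthy:
    - 0.7
    - 0.15
    - 0.15
    mdd:
    - 0.62
    - 0.16
    - 0.22
    bd:
    - 0.6
    - 0.17
    - 0.23
    sz:
    - 0.55
    - 0.18
    - 0.27
    other:
    - 0.68
    - 0.15
    - 0.17
- name: comorbidity_count
  category: physical
  type: ordinal
  levels:
  - 0
  - 1
  - 2
  - 3
  prob:
    healthy:
    - 0.65
    - 0.22
    - 0.09
    - 0.04
    mdd:
    - 0.55
    - 0.26
    - 0.12
    - 0.07
    bd:
    - 0.56
    - 0.25
    - 0.12
    - 0.07
    sz:
    - 0.5
    - 0.27
    - 0.14
    - 0.09
    other:
    - 0.6
    - 0.24
    - 0.1
    - 0.06
- name: employment
  category: social
  type: categorical
  levels:
  - fulltime
  - parttime
  - unemployed
  - retired
  prob:
    healthy:
    - 0.5
    - 0.2
    - 0.1
    - 0.2
    mdd:
    - 0.35
    - 0.25
    - 0.25
    - 0.15
    bd:
    - 0.33
    - 0.25
    - 0.27
    - 0.15
    sz:
    - 0.25
    - 0.25
    - 0.35
    - 0.15
    other:
    - 0.45
    - 0.22
    - 0.15
    - 0.18
- name: marital_status
  category: social
  type: categorical
  levels:
  - married
  - single
  - divorced_widowed
  prob:
    healthy:
    - 0.55
    - 0.35
    - 0.1
    mdd:
    - 0.45
    - 0.45
    - 0.1
    bd:
    - 0.42
    - 0.47
    - 0.11
    sz:
    - 0.3
    - 0.6
    - 0.1
    other:
    - 0.5
    - 0.4
    - 0.1
- name: household_income_band
  category: social
  type: ordinal
  levels:
  - 1
  - 2
  - 3
  - 4
  - 5
  prob:
    healthy:
    - 0.15
    - 0.25
    - 0.3
    - 0.2
    - 0.1
    mdd:
    - 0.25
    - 0.28
    - 0.27
    - 0.14
    - 0.06
    bd:
    - 0.25
    - 0.28
    - 0.27
    - 0.14
    - 0.06
    sz:
    - 0.32
    - 0.3
    - 0.24
    - 0.1
    - 0.04
    other:
    - 0.2
    - 0.27
    - 0.28
    - 0.17
    - 0.08
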