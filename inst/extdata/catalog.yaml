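# Attribute catalog for the financial-incentive smoking-cessation DCE:
# five program attributes; the incentive amount is continuous (pounds over
# the whole 10-week program), all others are effects coded. Preference
# directions (worst to best) are analyst assertions used only to build the
# dominance-check set and to reject dominated pairs during design search.
attributes:
- name: amount
  levels: [50.0, 100.0, 200.0, 350.0, 500.0, 750.0, 1000.0]
  coding: continuous
  preference_direction: increasing
- name: type
  levels: [Voucher, Cash]
  coding: effects
  omitted_level: Voucher
  preference_direction: [Voucher, Cash]
- name: schedule
  levels: [Escalating, Consistent]
  coding: effects
  omitted_level: Escalating
  preference_direction: [Escalating, Consistent]
- name: sessions
  levels: [1_fortnight, 1_week, 2_week, 3_week]
  coding: effects
  omitted_level: 3_week
  preference_direction: [3_week, 2_week, 1_fortnight, 1_week]
- name: location
  levels: [Workplace, Healthcare]
  coding: effects
  omitted_level: Workplace
  preference_direction: [Workplace, Healthcare]
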