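# Default scoring rubric for the six-item voluntary form.
# Higher scores mean a safer answer; per-item scores are capped by
# upper_bounds and phi is the normalized radar area of the six scores.
# Tier values are site configuration (regional risk tiers are defined by
# the local government), not epidemiological constants.
items:
  home:
    risk_tier_low: 5
    risk_tier_guarded: 4
    risk_tier_elevated: 3
    risk_tier_high: 2
    risk_tier_severe: 1
  workplace:
    risk_tier_low: 5
    risk_tier_guarded: 4
    risk_tier_elevated: 3
    risk_tier_high: 2
    risk_tier_severe: 1
  travel_record:
    none: 5
    domestic_low_risk: 4
    domestic_medium_risk: 3
    domestic_high_risk: 2
    international_or_outbreak_area: 1
  means_of_transport:
    walking: 5
    private_car: 4
    taxi: 3
    bus: 2
    metro: 1
  symptoms:
    none: 5
    mild: 2
    severe: 1
  close_contact:
    none: 5
    indirect: 2
    confirmed_case: 1
upper_bounds: [5, 5, 5, 5, 5, 5]
theta_liability: 0.8
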