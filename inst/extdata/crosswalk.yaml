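# Default annotation-schema / DSM-5 crosswalk.
#
# 27 classes, 18 of which score against the 11 DSM-5 OUD criteria:
#   1 larger amounts / longer than intended    7 activities given up
#   2 persistent desire / unsuccessful cutback 8 hazardous use
#   3 time spent obtaining/using/recovering    9 physical/psychological problems
#   4 craving                                 10 tolerance
#   5 role failure (work/school/home)         11 withdrawal
#   6 social/interpersonal problems
#
# The class -> criterion assignments below are a provisional mapping chosen
# for face validity; the crosswalk is configuration, not code, so a site can
# substitute its own chart-review-derived mapping without touching the
# package. "OUD treatment" (an order for medication treatment of OUD, e.g.
# buprenorphine) forces the severe category rather than granting criteria,
# so the numeric score stays interpretable.
version: "1.0"
expected_counts:
  total_classes: 27
  scoring_classes: 18
  attributed_classes: 12
classes:
  # --- opioid misuse -------------------------------------------------------
  - name: OUD
    category: opioid_misuse
    scoring: true
    criteria: [1]
  - name: OUD treatment
    category: opioid_misuse
    scoring: true
    force_category: severe
  - name: opioid misuse-prescription
    category: opioid_misuse
    scoring: true
    criteria: [1]
    attributes:
      temporality: [current, historic]
  - name: opioid misuse-illicit
    category: opioid_misuse
    scoring: true
    criteria: [8]
    attributes:
      temporality: [current, historic]
  - name: opioid craving
    category: opioid_misuse
    scoring: true
    criteria: [4]
    attributes:
      temporality: [current, historic]
  - name: opioid tolerance
    category: opioid_misuse
    scoring: true
    criteria: [10]
  - name: withdrawal
    category: opioid_misuse
    scoring: true
    criteria: [11]
    attributes:
      temporality: [current, historic]
  - name: intoxication
    category: opioid_misuse
    scoring: true
    criteria: [8]
    attributes:
      temporality: [current, historic]
  - name: naloxone
    category: opioid_misuse
    scoring: true
    criteria: [8]
  # --- lack of control -----------------------------------------------------
  - name: drug seeking
    category: lack_of_control
    scoring: true
    criteria: [3]
  - name: unsuccessful cutback
    category: lack_of_control
    scoring: true
    criteria: [2]
  - name: excessive opioid use
    category: lack_of_control
    scoring: true
    criteria: [1]
  - name: time spent obtaining opioids
    category: lack_of_control
    scoring: true
    criteria: [3]
  # --- consequences --------------------------------------------------------
  - name: vocational consequences
    category: consequence
    scoring: true
    criteria: [5]
    attributes:
      temporality: [current, historic]
  - name: social consequences
    category: consequence
    scoring: true
    criteria: [6]
    attributes:
      temporality: [current, historic]
  - name: activities given up
    category: consequence
    scoring: true
    criteria: [7]
  - name: opioid-related medical issues
    category: consequence
    scoring: true
    criteria: [9]
    attributes:
      temporality: [current, historic]
  # --- non-opioid substance use -------------------------------------------
  - name: overdose history
    category: substance_use_nonopioid
    scoring: true
    criteria: [8]
    attributes:
      temporality: [current, historic]
  - name: history of substance misuse
    category: substance_use_nonopioid
    scoring: false
    attributes:
      temporality: [current, historic]
  - name: daily tobacco use
    category: substance_use_nonopioid
    scoring: false
  - name: polysubstance misuse
    category: substance_use_nonopioid
    scoring: false
  - name: other illicit drug use
    category: substance_use_nonopioid
    scoring: false
    attributes:
      temporality: [current, historic]
  - name: alcohol misuse
    category: substance_use_nonopioid
    scoring: false
  # --- contributing factors ------------------------------------------------
  - name: psychiatric condition
    category: contributing_factor
    scoring: false
    attributes:
      temporality: [current, historic]
  - name: chronic pain
    category: contributing_factor
    scoring: false
  - name: family history of substance misuse
    category: contributing_factor
    scoring: false
  # --- other ---------------------------------------------------------------
  - name: social context
    category: other
    scoring: false
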