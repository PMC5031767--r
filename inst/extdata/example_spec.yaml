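# Example two-study specification. Population values are illustrative
# synthetic numbers, not estimates from any published experiment.
spec_version: 1
label: example_set
tes_threshold: 0.1
studies:
  - label: priming_study
    measures: [crime_relevant, crime_irrelevant]
    conditions:
      - label: white_prime
        sample_size: 13
        means: [28, 24]
        sds: [6, 6]
        correlations:
          - [1.0, 0.4]
          - [0.4, 1.0]
      - label: no_prime
        sample_size: 12
        means: [24, 24]
        sds: [6, 6]
        correlations:
          - [1.0, 0.4]
          - [0.4, 1.0]
      - label: black_prime
        sample_size: 14
        means: [20, 24]
        sds: [6, 6]
        correlations:
          - [1.0, 0.4]
          - [0.4, 1.0]
    tests:
      - id: rel_white_vs_black
        kind: between
        condition: white_prime
        condition_b: black_prime
        measure: crime_relevant
        required: significant
        expected_sign: positive
      - id: irr_white_vs_none
        kind: between
        condition: white_prime
        condition_b: no_prime
        measure: crime_irrelevant
        required: nonsignificant
      - id: within_white
        kind: within
        condition: white_prime
        measure: crime_relevant
        measure_b: crime_irrelevant
        required: significant
        expected_sign: positive
  - label: simple_followup
    measures: [rating]
    conditions:
      - label: control
        sample_size: 20
        means: [0]
        sds: [1]
      - label: treatment
        sample_size: 20
        means: [0.8]
        sds: [1]
    tests:
      - id: treatment_effect
        kind: between
        condition: treatment
        condition_b: control
        measure: rating
        required: significant
        expected_sign: positive
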