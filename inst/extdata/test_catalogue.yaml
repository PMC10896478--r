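# Cognitive test catalogue: every test belongs to exactly one domain and
# carries a direction flag. Timed tests (trail making, Stroop times) have
# higher_is_better: false and are sign-flipped after z-scoring.
tests:
  - {test: avlt_delayed_recall,      domain: episodic_memory,              higher_is_better: true}
  - {test: rocf_delayed_recall,      domain: episodic_memory,              higher_is_better: true}
  - {test: logical_memory_delayed,   domain: episodic_memory,              higher_is_better: true}
  - {test: clock_drawing,            domain: visuospatial_function,        higher_is_better: true}
  - {test: rocf_copy,                domain: visuospatial_function,        higher_is_better: true}
  - {test: digit_span,               domain: executive_function,           higher_is_better: true}
  - {test: trail_making_b_time,      domain: executive_function,           higher_is_better: false}
  - {test: verbal_fluency,           domain: executive_function,           higher_is_better: true}
  - {test: stroop_c_time,            domain: executive_function,           higher_is_better: false}
  - {test: semantic_similarity,      domain: executive_function,           higher_is_better: true}
  - {test: symbol_digit_modalities,  domain: information_processing_speed, higher_is_better: true}
  - {test: trail_making_a_time,      domain: information_processing_speed, higher_is_better: false}
  - {test: stroop_a_time,            domain: information_processing_speed, higher_is_better: false}
  - {test: stroop_b_time,            domain: information_processing_speed, higher_is_better: false}
  - {test: mmse,                     domain: global_cognition,             higher_is_better: true}
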