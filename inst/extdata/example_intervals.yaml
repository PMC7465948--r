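# Example retention-interval definition: half-open [start, end) minutes.
# Overlapping intervals are rejected unless load_interval_config() is
# called with allow_overlap = TRUE (deliberate re-coverage of unresolved
# regions is sometimes useful).
- start: 8.40
  end: 8.57
  label: coelution-window
- start: 8.57
  end: 8.70
  label: late-window
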