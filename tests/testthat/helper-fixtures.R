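# Shared fixtures: small participant tables built in code from schema-named
# columns, so feature-kind lookups behave as in real tables.

fixture_schema <- build_feature_schema()

# a participant_table with arbitrary columns drawn from the schema
tiny_table <- function(X, y = NULL, timestamps = NULL, id = "T-1") {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(y)) y <- rep(c(2L, 3L, 4L), length.out = n)
  if (is.null(timestamps))
    timestamps <- as.POSIXct("2024-01-01 08:00:00", tz = "UTC") +
      (seq_len(n) - 1) * 6 * 3600
  moodcast:::new_participant_table(timestamps, X, y, fixture_schema, id)
}

# deterministic planted-signal cohort used in several suites
planted_table <- function(effect = 2, noise = 0.25, seed = 42,
                          missing_rate = 0) {
  spec <- cohort_spec(planted_effects = c("anxious" = effect),
                      noise_sd = noise, missing_rate = missing_rate,
                      label_skew = 0, seed = seed)
  generate_participant(spec, "P-fix")
}

# simple deterministic objective on the encoded cube (unimodal)
sphere_objective <- function(cand) {
  v <- encode_candidate(cand)
  sum((v - 0.5)^2)
}
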