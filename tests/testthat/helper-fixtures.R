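# shared small fixtures, built once per test run

# a single default-world segment reused by extractor tests
fix_segment <- function() {
  if (is.null(.fix_env$segment))
    .fix_env$segment <- generate_segment(1, 1, effect_config(), seed = 101)
  .fix_env$segment
}

# an all-zero segment (degenerate input)
zero_segment <- function() {
  seg <- fix_segment()
  seg$data[] <- 0
  seg
}

# tiny one-subject collection: 6 classes x 4 segments
fix_collection <- function() {
  if (is.null(.fix_env$collection))
    .fix_env$collection <- generate_dataset(1, 4, effect_config(),
                                            seed = 202)[[1]]
  .fix_env$collection
}

# its ND feature table (smallest domain; used by classify tests)
fix_nd_table <- function() {
  if (is.null(.fix_env$nd_table))
    .fix_env$nd_table <- build_feature_table(fix_collection(), sets = "ND")
  .fix_env$nd_table
}

.fix_env <- new.env(parent = emptyenv())

# an effect config with a single planted alpha-band effect
planted_alpha_cfg <- function(multiplier = 4, channels = c(8L, 9L, 10L),
                              gain_sd = 0.2) {
  m <- matrix(1, 6, 5)
  m[1, 3] <- multiplier                   # class 1, alpha band
  effect_config(multipliers = m, affected_channels = channels,
                subject_gain_sd = gain_sd)
}

# fully separable world: class c boosts band c (c = 1..5), class 6 baseline
separable_cfg <- function(multiplier = 8) {
  m <- matrix(1, 6, 5)
  for (c in 1:5) m[c, c] <- multiplier
  effect_config(multipliers = m)
}
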