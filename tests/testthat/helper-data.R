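# Shared fixtures: all data are generated in code at test time.

# A desk-scale scenario; override any knob via ...
tiny_scenario <- function(n_sample1 = 8000, n_sample2 = 800, seed = 42, ...) {
  sim_scenario(n_sample1 = n_sample1, n_sample2 = n_sample2, seed = seed, ...)
}

# Three-disease scenario used for recovery checks: a real effect, a null,
# and a small effect for CI coverage.
recovery_specs <- function() {
  data.frame(name = c("disease_A", "disease_B", "disease_C"),
             baseline_prevalence = c(0.12, 0.12, 0.12),
             causal_beta = c(-0.5, 0, -0.3),
             stringsAsFactors = FALSE)
}

# Random EHR-style prescription table for fuzz tests.
random_prescriptions <- function(n_records, ids, date_lo, date_hi) {
  codes <- c("J01CR02", "J01FA09", "J01MA02", "J01CA04", "J01DB05",
             "N02BE01", "A02BC02", "J01XE01")
  span <- as.integer(date_hi - date_lo)
  data.frame(
    person_id = sample(ids, n_records, replace = TRUE),
    date = date_lo + sample.int(span + 1L, n_records, replace = TRUE) - 1L,
    atc_code = sample(codes, n_records, replace = TRUE),
    stringsAsFactors = FALSE)
}
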