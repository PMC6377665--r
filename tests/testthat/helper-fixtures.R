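# Small in-code fixtures shared across test files.

tiny_weights <- function() {
  probe_weights(c("cg1", "cg2", "cg3"), c(0.5, -1.0, 0.25))
}

tiny_betas <- function() {
  as_beta_matrix(matrix(c(0.2, 0.4, 0.8,
                          0.1, 0.6, 0.3),
                        nrow = 3,
                        dimnames = list(c("cg1", "cg2", "cg3"),
                                        c("s1", "s2"))))
}

write_weight_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# two-wave records built directly at the record level (no probe layer):
# group-specific mean changes plus Gaussian change noise
make_records <- function(seed, effects = c(never = 0, quit_by_w1 = 0,
                                           quit_between = -0.25,
                                           current_at_w2 = 0.49),
                         n = c(never = 405, quit_by_w1 = 100,
                               quit_between = 40, current_at_w2 = 124),
                         noise_sd = 0.5) {
  set.seed(seed)
  group <- rep(names(n), n)
  y1 <- rnorm(sum(n))
  y2 <- y1 + effects[group] + rnorm(sum(n), 0, noise_sd)
  two_wave_records(sprintf("s%04d", seq_along(group)), y1, y2, group,
                   standardize = "none")
}
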