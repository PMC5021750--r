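# Small experimental designs for fast unit fits; the full 12-clone design
# is exercised in the acceptance tests.

small_config <- function(n_clones = 4, n_replicates = 2,
                         epa_grid = c(0, 0.5, 1.5, 4, 10),
                         residual_sd = 0.02,
                         re_g0 = 0.03, re_ginf = 0, re_ks = 0) {
  cfg <- default_config()
  keep <- cfg$clones$clone_id[round(seq(1, 12, length.out = n_clones))]
  cfg$clones <- cfg$clones[cfg$clones$clone_id %in% keep, , drop = FALSE]
  rownames(cfg$clones) <- NULL
  cfg$true_g0_by_clone <- cfg$true_g0_by_clone[keep]
  cfg$true_ginf_by_clone <- cfg$true_ginf_by_clone[keep]
  cfg$epa_grid <- epa_grid
  cfg$n_replicates <- as.integer(n_replicates)
  cfg$residual_sd <- residual_sd
  cfg$random_effect_sd <- c(g0 = re_g0, ginf = re_ginf, KS = re_ks)
  cfg
}

noise_free_config <- function(...) {
  small_config(residual_sd = 0, re_g0 = 0, re_ginf = 0, re_ks = 0, ...)
}

# Tie-corrected Kruskal-Wallis H by the explicit rank formula: an
# independent oracle for the packaged test.
kw_oracle_h <- function(groups) {
  x <- unlist(groups)
  n <- length(x)
  rk <- rank(x)
  sizes <- vapply(groups, length, integer(1))
  idx <- rep(seq_along(groups), sizes)
  rsums <- tapply(rk, idx, sum)
  h <- 12 / (n * (n + 1)) * sum(rsums^2 / sizes) - 3 * (n + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}
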