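test_that("AIC arithmetic is exact", {
  expect_equal(aic(567.8, 6), -1123.6)
  expect_equal(aic(0, 0), 0)
  expect_equal(aic(123.4, 8) - aic(123.4, 7), 2)
})

test_that("likelihood-ratio test matches the chi-square tail", {
  mkfit <- function(name, ll, df) structure(
    list(spec = model_spec(name), logLik = ll, Df = df, converged = TRUE),
    class = "monod_fit")

  same <- lr_test(mkfit("A1", 500, 5), mkfit("B1", 500, 6))
  expect_equal(same$chisq, 0)
  expect_equal(same$chi_df, 1)
  expect_equal(same$p_value, 1)

  lt <- lr_test(mkfit("A1", 565.2, 5), mkfit("B1", 567.8, 6))
  expect_equal(lt$chisq, 5.2)
  expect_equal(lt$p_value, stats::pchisq(5.2, 1, lower.tail = FALSE))
  expect_equal(lt$p_value, 0.0226, tolerance = 1e-3)

  # quantile identity: chisq = 3.841 on 1 df is the 5% point
  q <- lr_test(mkfit("A1", 100, 5), mkfit("B1", 100 + 3.841 / 2, 6))
  expect_equal(q$p_value, 0.05, tolerance = 1e-3)

  # invariant to adding a constant to both log-likelihoods
  sh <- lr_test(mkfit("A1", 565.2 + 1000, 5), mkfit("B1", 567.8 + 1000, 6))
  expect_equal(sh$chisq, lt$chisq)

  expect_error(lr_test(mkfit("A1", 1, 5), mkfit("B2", 2, 7)), "nested")
  expect_error(lr_test(mkfit("B1", 1, 6), mkfit("B1", 2, 6)), "nested")
  nc <- mkfit("A1", 1, 5); nc$converged <- FALSE
  expect_error(lr_test(nc, mkfit("B1", 2, 6)), "converged")
})

test_that("model series table is internally consistent and picks min AIC", {
  cfg <- small_config(n_clones = 6, n_replicates = 2)
  g <- simulate_growth(cfg, seed = 3)
  sel <- run_model_series(g, cfg$clones)
  tab <- sel$table
  expect_equal(tab$model, c("A1", "A2", "A3", "B1", "B2", "B3"))
  expect_equal(tab$AIC, aic(tab$logLik, tab$Df), tolerance = 1e-9)
  expect_equal(tab$Df, c(5L, 6L, 7L, 6L, 7L, 8L))
  ok <- tab$converged
  expect_equal(sel$best_model, tab$model[ok][which.min(tab$AIC[ok])])
  if (!is.null(sel$pairwise_tests)) {
    expect_true(all(sel$pairwise_tests$chi_df == 1))
    expect_true(all(sel$pairwise_tests$chisq >= 0))
  }
  expect_output(print(sel), "Best model")
})

test_that("residual bootstrap is deterministic and vanishes without noise", {
  cfg <- noise_free_config(n_clones = 4, n_replicates = 2)
  g <- simulate_growth(cfg, seed = 1)
  fit <- fit_nlme(g, cfg$clones, "B1")
  boot <- residual_bootstrap(fit, n_boot = 10, seed = 5)
  expect_true(all(boot$summary$ks_se < 1e-4))
  expect_true(all(boot$summary$s75_se < 1e-4))

  cfg2 <- small_config()
  g2 <- simulate_growth(cfg2, seed = 2)
  fit2 <- fit_nlme(g2, cfg2$clones, "B1")
  b1 <- residual_bootstrap(fit2, n_boot = 12, seed = 9)
  b2 <- residual_bootstrap(fit2, n_boot = 12, seed = 9)
  expect_identical(b1$summary, b2$summary)
  expect_false(identical(
    b1$summary$ks_boot,
    residual_bootstrap(fit2, n_boot = 12, seed = 10)$summary$ks_boot))

  expect_equal(b1$summary$s75, 3 * b1$summary$ks, tolerance = 1e-12)
  expect_error(residual_bootstrap(fit2, n_boot = 1, seed = 1), "n_boot")

  # fixed-variance mode runs and reports the same point estimates
  bf <- residual_bootstrap(fit2, n_boot = 8, seed = 3,
                           refit_variance = FALSE)
  expect_equal(bf$summary$ks, b1$summary$ks)
})

test_that("bootstrap intervals widen with the residual noise of the design", {
  widths <- vapply(c(0.01, 0.05), function(sd) {
    cfg <- small_config(residual_sd = sd)
    g <- simulate_growth(cfg, seed = 4)
    fit <- fit_nlme(g, cfg$clones, "B1")
    b <- residual_bootstrap(fit, n_boot = 40, seed = 6)
    mean(b$summary$ks_hi - b$summary$ks_lo)
  }, numeric(1))
  expect_lt(widths[1], widths[2])
})

test_that("bootstrap percentile intervals cover the true size-law slope", {
  cfg <- small_config(n_clones = 6, n_replicates = 2)
  hits <- 0; runs <- 20
  for (sd in seq_len(runs)) {
    g <- simulate_growth(cfg, seed = 400 + sd)
    fit <- fit_nlme(g, cfg$clones, "B1")
    if (!fit$converged) next
    b <- residual_bootstrap(fit, n_boot = 50, seed = 500 + sd)
    kl <- b$fixed[b$fixed$parameter == "KL", ]
    if (kl$lo <= cfg$true_KL && cfg$true_KL <= kl$hi) hits <- hits + 1
  }
  expect_gte(hits / runs, 0.8)
})
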