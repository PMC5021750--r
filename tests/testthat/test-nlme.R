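test_that("per-clone least squares matches an exhaustive grid search", {
  cfg <- small_config(n_clones = 1, n_replicates = 3,
                      epa_grid = c(0, 0.5, 1, 2, 4, 7, 10))
  g <- simulate_growth(cfg, seed = 8)   # one clone, 21 observations
  fit <- fit_per_clone_nls(g)

  # brute-force oracle: exhaustive grid over (g0, ginf, KS)
  g0_grid <- seq(0.05, 0.35, by = 0.005)
  gi_grid <- seq(0.35, 0.75, by = 0.005)
  ks_grid <- exp(seq(log(0.05), log(10), length.out = 120))
  best <- c(Inf, NA, NA, NA)  # rss, g0, ginf, ks
  for (ks in ks_grid) {
    u <- g$epa_conc_S / (g$epa_conc_S + ks)
    for (gi in gi_grid) {
      r0 <- g$growth_rate_g - gi * u
      for (g0 in g0_grid) {
        rss <- sum((r0 - g0 * (1 - u))^2)
        if (rss < best[1]) best <- c(rss, g0, gi, ks)
      }
    }
  }
  cell <- diff(log(ks_grid))[1]
  expect_lt(abs(log(fit$params$KS) - log(best[4])), 1.5 * cell)
  expect_lte(fit$rss, best[1] + 1e-12)

  # degenerate flat data: KS not identifiable, ginf collapses onto g0
  flat <- g; flat$growth_rate_g <- rep(0.2, nrow(flat))
  expect_warning(ffit <- fit_per_clone_nls(flat), "flat likelihood")
  expect_false(ffit$identifiable)
  expect_equal(ffit$params$g0, ffit$params$ginf)

  expect_error(fit_per_clone_nls(data.frame(epa_conc_S = c(0, 1, 2),
                                            growth_rate_g = c(1, 2, 3))),
               "4 distinct")
})

test_that("noise-free mixed fits recover the generative parameters", {
  cfg <- noise_free_config(n_clones = 4, n_replicates = 2)
  g <- simulate_growth(cfg, seed = 1)
  truth <- true_clone_params(cfg)

  fb <- fit_nlme(g, cfg$clones, "B1")
  expect_true(fb$converged)
  expect_lt(abs(fb$fixed_estimates[["K0"]] - cfg$true_K0), 1e-4)
  expect_lt(abs(fb$fixed_estimates[["KL"]] - cfg$true_KL), 1e-4)
  expect_lt(abs(fb$fixed_estimates[["ginf"]] - 0.55), 1e-5)
  expect_lt(max(abs(fb$clone_params$g0 - truth$g0)), 1e-4)
  expect_lt(max(abs(residuals(fb))), 1e-6)

  # fully homogeneous truth: random-effect sd collapses to zero and the
  # fixed effects equal the generative values
  u <- cfg
  u$true_g0_by_clone[] <- 0.25
  gu <- simulate_growth(u, seed = 1)
  fu <- fit_nlme(gu, u$clones, "B1")
  expect_true(fu$converged)
  expect_lt(fu$random_sd[["g0"]], 1e-5)
  expect_lt(abs(fu$fixed_estimates[["g0"]] - 0.25), 1e-5)
  expect_lt(abs(fu$fixed_estimates[["ginf"]] - 0.55), 1e-5)
  expect_lt(abs(fu$fixed_estimates[["K0"]] - u$true_K0), 1e-4)
  expect_lt(abs(fu$fixed_estimates[["KL"]] - u$true_KL), 1e-4)

  # family A on data with a single common KS
  cfgA <- cfg
  cfgA$true_KL <- 0
  cfgA$true_K0 <- 1.1
  gA <- simulate_growth(cfgA, seed = 1)
  fa <- fit_nlme(gA, cfgA$clones, "A1")
  expect_true(fa$converged)
  expect_lt(abs(fa$fixed_estimates[["KS"]] - 1.1), 1e-4)
})

test_that("Df counting follows the fixed + variance + residual convention", {
  expect_equal(
    vapply(c(A1 = "A1", A2 = "A2", A3 = "A3"), function(m)
      3L + model_spec(m)$q + 1L, integer(1)),
    c(A1 = 5L, A2 = 6L, A3 = 7L))
  cfg <- small_config()
  g <- simulate_growth(cfg, seed = 2)
  f <- fit_nlme(g, cfg$clones, "B1")
  expect_equal(f$Df, 6L)
  expect_equal(f$AIC, 2 * f$Df - 2 * f$logLik)
  ll <- logLik(f)
  expect_s3_class(ll, "logLik")
  expect_equal(AIC(ll), f$AIC)
})

test_that("Laplace log-likelihood matches adaptive Gauss-Hermite quadrature", {
  cfg <- small_config(n_clones = 3, n_replicates = 2, re_g0 = 0.03)
  g <- simulate_growth(cfg, seed = 21)
  fit <- fit_nlme(g, cfg$clones, "A1")
  expect_true(fit$converged)
  prep <- monodmix:::.prep_growth_data(g, cfg$clones)
  prep$Llo <- min(prep$L); prep$Lhi <- max(prep$L)
  agq <- monodmix:::.agq_loglik(fit$par, fit$spec, prep, nodes = 20)
  expect_lt(abs(fit$logLik - agq), 0.05)

  fitB <- fit_nlme(g, cfg$clones, "B1")
  agqB <- monodmix:::.agq_loglik(fitB$par, fitB$spec, prep, nodes = 20)
  expect_lt(abs(fitB$logLik - agqB), 0.05)
})

test_that("with variance components at zero the marginal equals pooled NLS", {
  cfg <- small_config(n_clones = 3, n_replicates = 2, re_g0 = 0.02)
  g <- simulate_growth(cfg, seed = 31)
  prep <- monodmix:::.prep_growth_data(g, cfg$clones)
  prep$Llo <- min(prep$L); prep$Lhi <- max(prep$L)
  pooled <- monodmix:::.pooled_nls(prep$S, prep$y)
  sig <- sqrt(pooled$rss / prep$n)
  par <- c(pooled$g0, pooled$ginf, log(pooled$KS), 0, sig)
  nll <- monodmix:::.laplace_nll(par, model_spec("A1"), prep)
  expect_lt(abs(-nll - monodmix:::.pooled_loglik(prep$S, prep$y)), 1e-6)
})

test_that("clone-level predictions combine fixed effects, size law and deviations", {
  cfg <- small_config(re_g0 = 0.04)
  g <- simulate_growth(cfg, seed = 12)
  fit <- fit_nlme(g, cfg$clones, "B1")
  cp <- fit$clone_params
  cl <- cp$clone_id[2]

  expect_equal(predict_growth(fit, cl, 0), cp$g0[2])
  expect_lt(abs(predict_growth(fit, cl, 1e6) - cp$ginf[2]), 1e-4)
  expect_equal(predict_growth(fit, cl, cp$KS[2]),
               (cp$g0[2] + cp$ginf[2]) / 2)
  # clone total = fixed effect + predicted deviation
  expect_equal(cp$g0[2],
               fit$fixed_estimates[["g0"]] + fit$clone_deviations$g0[2])

  expect_warning(p <- predict_growth(fit, "nobody", 1, L = 2.5),
                 "population-level")
  fe <- fit$fixed_estimates
  ks <- fe[["K0"]] + fe[["KL"]] * 2.5
  expect_equal(p, fe[["g0"]] + (fe[["ginf"]] - fe[["g0"]]) * 1 / (1 + ks))
  expect_error(predict_growth(fit, "nobody", 1), "body size")

  fitA <- fit_nlme(g, cfg$clones, "A1")
  expect_warning(pA <- predict_growth(fitA, "nobody", 0), "fixed-effects")
  expect_equal(pA, fitA$fixed_estimates[["g0"]])
})

test_that("likelihoods respect the nesting order across the model series", {
  for (sd in c(2, 14)) {
    cfg <- small_config(n_clones = 6, n_replicates = 2)
    g <- simulate_growth(cfg, seed = sd)
    sel <- run_model_series(g, cfg$clones)
    ll <- setNames(sel$table$logLik, sel$table$model)
    slack <- 1e-3
    expect_gte(ll[["A3"]], ll[["A2"]] - slack)
    expect_gte(ll[["A2"]], ll[["A1"]] - slack)
    for (k in 1:3)
      expect_gte(ll[[paste0("B", k)]], ll[[paste0("A", k)]] - slack)
  }
})

test_that("mixed fit agrees with an independent nlme implementation", {
  skip_if_not_installed("nlme")
  cfg <- small_config(n_clones = 6, n_replicates = 3,
                      residual_sd = 0.005, re_g0 = 0.01)
  g <- simulate_growth(cfg, seed = 77)
  fit <- fit_nlme(g, cfg$clones, "A1")
  ref <- nlme::nlme(
    growth_rate_g ~ g0 + (ginf - g0) * epa_conc_S / (epa_conc_S + KS),
    fixed = g0 + ginf + KS ~ 1,
    random = g0 ~ 1 | clone_id,
    data = g,
    start = c(g0 = 0.3, ginf = 0.55, KS = 1),
    method = "ML")
  fe <- nlme::fixef(ref)
  expect_lt(abs(fit$fixed_estimates[["g0"]] - fe[["g0"]]), 0.02)
  expect_lt(abs(fit$fixed_estimates[["ginf"]] - fe[["ginf"]]), 0.02)
  expect_lt(abs(fit$fixed_estimates[["KS"]] - fe[["KS"]]), 0.05)
  expect_lt(abs(fit$logLik - as.numeric(stats::logLik(ref))), 0.5)
})

test_that("clutch series drops eggless clones and recovers a transform-scale truth", {
  cfg <- default_config()
  clutch <- simulate_clutch(cfg, seed = 9)
  fit <- fit_clutch_series(clutch, cfg$clones, "B1")
  expect_true(fit$converged)
  expect_setequal(fit$dropped_clones, cfg$eggless_clones)
  expect_false(any(fit$clone_deviations$clone_id %in% cfg$eggless_clones))

  # zero-noise data built to be Monod on the transformed scale: exact recovery
  cl <- cfg$clones[cfg$clones$clone_id %in%
                     c("DlE", "DpBrA3", "DpGr8", "IL-M1-8"), ]
  truth <- true_clone_params(cfg)
  truth <- truth[match(cl$clone_id, truth$clone_id), ]
  scale <- 3
  grid <- expand.grid(replicate = 1:2, epa_conc_S = cfg$epa_grid,
                      clone_id = cl$clone_id, stringsAsFactors = FALSE)
  i <- match(grid$clone_id, truth$clone_id)
  tprime <- 0.1 + (0.8 - 0.1) * grid$epa_conc_S /
    (grid$epa_conc_S + truth$KS[i])
  grid$clutch_size_c <- scale * arcsin_sqrt_inverse(tprime)
  fit0 <- fit_clutch_series(grid, cl, "B1", scale = scale)
  expect_lt(abs(fit0$fixed_estimates[["g0"]] - 0.1), 1e-4)
  expect_lt(abs(fit0$fixed_estimates[["ginf"]] - 0.8), 1e-4)
  expect_lt(abs(fit0$fixed_estimates[["K0"]] - cfg$true_K0), 2e-3)
  expect_lt(abs(fit0$fixed_estimates[["KL"]] - cfg$true_KL), 1e-3)

  eggless_all <- clutch
  eggless_all$clutch_size_c <- 0
  expect_error(fit_clutch_series(eggless_all, cfg$clones, "B1"), "eggless")
})

test_that("the transform stabilises the clutch mean-variance relation", {
  cfg <- default_config()
  clutch <- simulate_clutch(cfg, seed = 40)
  keep <- !(clutch$clone_id %in% cfg$eggless_clones) & clutch$epa_conc_S > 0
  cc <- clutch[keep, ]
  cell <- interaction(cc$clone_id, cc$epa_conc_S)
  raw_mean <- tapply(cc$clutch_size_c, cell, mean)
  raw_sd <- tapply(cc$clutch_size_c, cell, sd)
  tr <- arcsin_sqrt_transform(cc$clutch_size_c / max(cc$clutch_size_c))
  tr_mean <- tapply(tr, cell, mean)
  tr_sd <- tapply(tr, cell, sd)
  rho_raw <- abs(cor(raw_mean, raw_sd, method = "spearman"))
  rho_tr <- abs(cor(tr_mean, tr_sd, method = "spearman"))
  expect_lt(rho_tr, rho_raw)
})
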