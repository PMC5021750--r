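test_that("default configuration reproduces the reference clone panel", {
  cfg <- default_config()
  expect_equal(nrow(cfg$clones), 12)
  expect_equal(range(cfg$clones$body_size_L), c(1.43, 3.54))
  expect_equal(length(cfg$epa_grid), 7)
  expect_equal(range(cfg$epa_grid), c(0, 10))

  # true half-saturation constants reproduce the bundled per-clone table
  truth <- true_clone_params(cfg)
  ref <- ks_reference()
  expect_true(all(abs(truth$KS - ref$ks) <= 0.02))
  expect_equal(truth$KS[truth$clone_id == "Dg"], 0.60, tolerance = 0.01)

  # species-level baseline growth anchors
  expect_equal(unname(cfg$true_g0_by_clone[["IL-M1-8"]]), 0.432)
  expect_equal(unname(cfg$true_g0_by_clone[["DpBrS"]]), 0.312)
  expect_equal(unname(cfg$true_g0_by_clone[["DlE"]]), 0.174)

  expect_silent(validate_config(cfg))
  bad <- cfg; bad$epa_grid <- c(0, 2, 1)
  expect_error(validate_config(bad), "increasing")
  bad <- cfg; bad$residual_sd <- -1
  expect_error(validate_config(bad), "residual_sd")
  bad <- cfg; bad$true_K0 <- -5
  expect_error(validate_config(bad), "non-positive KS")
})

test_that("growth simulation is deterministic and exact in the noise-free limit", {
  cfg <- default_config()
  g1 <- simulate_growth(cfg, seed = 42)
  g2 <- simulate_growth(cfg, seed = 42)
  expect_identical(g1, g2)
  expect_equal(nrow(g1), 12 * 7 * 3)
  expect_false(identical(g1$growth_rate_g,
                         simulate_growth(cfg, seed = 43)$growth_rate_g))

  nf <- cfg
  nf$residual_sd <- 0
  nf$random_effect_sd <- c(g0 = 0, ginf = 0, KS = 0)
  g <- simulate_growth(nf, seed = 1)
  truth <- true_clone_params(nf)
  i <- match(g$clone_id, truth$clone_id)
  mu <- truth$g0[i] + (truth$ginf[i] - truth$g0[i]) *
    g$epa_conc_S / (g$epa_conc_S + truth$KS[i])
  expect_equal(g$growth_rate_g, mu)

  # stored masses are consistent with the stored growth rate
  expect_equal(juvenile_growth_rate(g1$mass_initial_W0, g1$mass_final_Wt,
                                    g1$duration_t),
               g1$growth_rate_g)
})

test_that("sample mean growth at S = 0 converges to the true baseline", {
  cfg <- small_config(n_clones = 2, n_replicates = 1500, re_g0 = 0)
  g <- simulate_growth(cfg, seed = 99)
  cl <- cfg$clones$clone_id[1]
  x <- g$growth_rate_g[g$clone_id == cl & g$epa_conc_S == 0]
  expect_equal(length(x), 1500)
  se <- cfg$residual_sd / sqrt(1500)
  expect_lt(abs(mean(x) - cfg$true_g0_by_clone[[cl]]), 3 * se)
})

test_that("noise-free per-clone least squares recovers the size law exactly", {
  cfg <- default_config()
  cfg$residual_sd <- 0
  cfg$random_effect_sd <- c(g0 = 0, ginf = 0, KS = 0)
  g <- simulate_growth(cfg, seed = 1)
  truth <- true_clone_params(cfg)
  for (cl in truth$clone_id[c(1, 5, 12)]) {
    fit <- fit_per_clone_nls(g[g$clone_id == cl, ])
    expect_lt(abs(fit$params$KS - truth$KS[truth$clone_id == cl]), 1e-8)
  }
})

test_that("clutch simulation honours anchors, eggless clones and noise-free limit", {
  cfg <- default_config()
  cl <- simulate_clutch(cfg, seed = 7)
  expect_true(all(cl$clutch_size_c[cl$clone_id %in% cfg$eggless_clones] == 0))
  expect_true(all(cl$clutch_size_c >= 0))

  sp <- cfg$clones$species[match(cl$clone_id, cfg$clones$clone_id)]
  m_magna <- mean(cl$clutch_size_c[sp == "magna"])
  expect_equal(m_magna, 2.48, tolerance = 0.1)

  nf <- cfg; nf$clutch_disp <- 0
  cl0 <- simulate_clutch(nf, seed = 7)
  pars <- attr(cl0, "clutch_params")
  i <- match(cl0$clone_id, pars$clone_id)
  mu <- pars$c_inf[i] * cl0$epa_conc_S / (cl0$epa_conc_S + pars$KS[i])
  expect_equal(cl0$clutch_size_c, mu)
  # per-clone grid mean sits exactly on the species anchor
  anchors <- cfg$clutch_anchor_by_species[
    cfg$clones$species[match(pars$clone_id, cfg$clones$clone_id)]]
  grid_means <- tapply(mu, cl0$clone_id, mean)[pars$clone_id]
  laying <- !(pars$clone_id %in% cfg$eggless_clones)
  expect_equal(as.numeric(grid_means[laying]), unname(anchors[laying]))
})

test_that("fatty-acid simulation centres on the reference tables", {
  cfg <- default_config()
  nf <- cfg; nf$fa_sdlog <- 0; nf$dwt_sd <- 0
  fa <- simulate_fattyacids(nf, seed = 3)
  centers <- attr(fa, "centers")
  neo <- fa[fa$stage == "neonate", ]
  agg <- aggregate(neo[c("lin_18_2w6", "epa_20_5w3", "other_fa")],
                   by = list(clone_id = neo$clone_id), FUN = mean)
  i <- match(agg$clone_id, centers$neonate$clone_id)
  expect_equal(agg$epa_20_5w3, centers$neonate$epa_20_5w3[i])
  expect_equal(agg$other_fa, centers$neonate$other_fa[i])

  # constructed identity: total omega-3 = total PUFA - linoleic content
  fa2 <- simulate_fattyacids(cfg, seed = 4)
  tot <- fa_totals(fa2)
  ok <- !is.na(tot$total_pufa)
  expect_equal(tot$total_omega3[ok],
               (tot$total_pufa - fa2$lin_18_2w6)[ok])

  # dry masses centre on the configured sample means
  big <- cfg; big$n_fa_replicates <- 300L
  fab <- simulate_fattyacids(big, seed = 5)
  m0 <- mean(fab$dry_mass_ug[fab$stage == "neonate"])
  expect_lt(abs(m0 - 489.55), 3 * 32.21 / sqrt(300 * 8))

  # zero-noise tissue quotas reproduce the new-biomass reference
  quo <- tissue_quota_table(fa)
  ref <- fa_reference("new_biomass")
  i <- match(quo$clone_id, ref$clone_id)
  expect_equal(quo$total_fa, ref$total_fa[i], tolerance = 1e-10)
  ok <- !is.na(ref$epa[i])
  expect_equal(quo$epa[ok], ref$epa[i][ok], tolerance = 1e-10)
  expect_true(all(is.na(quo$total_pufa[!ok])))  # below detection propagates
})

test_that("simulate_dataset writes the four CSV schemas", {
  dir <- tempfile("simdat-")
  paths <- simulate_dataset(small_config(), seed = 2, out_dir = dir)
  expect_true(all(file.exists(paths)))
  back <- read_growth_table(paths["growth"], paths["clones"])
  expect_equal(nrow(back$growth), nrow(simulate_growth(small_config(), 2)))
})
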