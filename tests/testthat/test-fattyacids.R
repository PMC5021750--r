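test_that("fatty-acid totals follow the PUFA/omega-3 definitions", {
  zero <- data.frame(lin_18_2w6 = 0, ala_18_3w3 = 0, ete_20_3w3 = 0,
                     epa_20_5w3 = 0, other_fa = 0)
  expect_equal(unlist(fa_totals(zero)), c(total_fa = 0, total_pufa = 0,
                                          total_omega3 = 0, epa = 0))

  p <- data.frame(lin_18_2w6 = 1, ala_18_3w3 = 2, ete_20_3w3 = 3,
                  epa_20_5w3 = 4, other_fa = 7)
  tot <- fa_totals(p)
  expect_equal(tot$total_pufa, 10)
  expect_equal(tot$total_omega3, 9)
  expect_equal(tot$total_fa, 17)
  expect_equal(tot$epa, 4)

  set.seed(2)
  rnd <- as.data.frame(matrix(runif(5 * 30, 0, 50), ncol = 5))
  names(rnd) <- c("lin_18_2w6", "ala_18_3w3", "ete_20_3w3", "epa_20_5w3",
                  "other_fa")
  tt <- fa_totals(rnd)
  expect_equal(tt$total_omega3, tt$total_pufa - rnd$lin_18_2w6)
  expect_true(all(tt$total_pufa <= tt$total_fa))

  expect_error(fa_totals(rnd[, -1]), "lin_18_2w6")
})

test_that("newly built biomass content follows the mass-balance formula", {
  mk <- function(mass, fa, clone = "c1")
    list(clone_id = clone, dry_mass_ug = mass, total_fa = fa)

  hom <- newly_built_biomass_content(mk(100, 40), mk(300, 40))
  expect_equal(hom$content_new_biomass, 40)   # homogeneous tissue
  expect_false(hom$depleted)

  q <- newly_built_biomass_content(mk(100, 40), mk(300, 60))
  expect_equal(q$content_new_biomass, (60 * 300 - 40 * 100) / 200)  # 70

  # invariant to rescaling both masses by a common factor
  q2 <- newly_built_biomass_content(mk(100 * 3.7, 40), mk(300 * 3.7, 60))
  expect_equal(q2$content_new_biomass, q$content_new_biomass)

  dep <- newly_built_biomass_content(mk(100, 80), mk(150, 20))
  expect_true(dep$depleted)
  expect_lt(dep$content_new_biomass, 0)

  expect_error(newly_built_biomass_content(mk(300, 40), mk(100, 60)),
               "no growth")
  expect_error(newly_built_biomass_content(mk(100, 40), mk(300, 60, "c2")),
               "different clones")
})

test_that("species means are unweighted means of clone means", {
  clones <- default_config()$clones
  quo <- fa_reference("new_biomass")
  tab <- species_mean_table(quo, clones)
  pick <- function(sp, an) tab$mean[tab$species == sp & tab$analyte == an]
  expect_equal(pick("pulicaria", "total_fa"), 89.51, tolerance = 0.005)
  expect_equal(pick("magna", "total_fa"), 52.30, tolerance = 0.005)

  neo <- fa_reference("neonate")
  ntab <- species_mean_table(neo, clones)
  npick <- function(sp, an) ntab$mean[ntab$species == sp &
                                        ntab$analyte == an]
  expect_equal(npick("longispina_complex", "total_fa"), 41.58,
               tolerance = 0.005)
  expect_equal(npick("longispina_complex", "total_omega3"), 21.30,
               tolerance = 0.005)

  # missing analyte (below detection) reduces the divisor
  kl <- tab[tab$species == "longispina_complex" &
              tab$analyte == "total_pufa", ]
  expect_equal(kl$n_clones, 1)          # only Dl4 contributes
  expect_equal(kl$mean, 5.53)
  expect_true(is.na(kl$se))             # single clone: SE undefined

  # sample-level input is averaged within clone first
  samples <- quo[rep(1:nrow(quo), each = 2), ]
  samples$total_fa <- samples$total_fa + c(-1, 1)  # clone means unchanged
  tab2 <- species_mean_table(samples, clones)
  expect_equal(tab2$mean[tab2$analyte == "total_fa"],
               tab$mean[tab$analyte == "total_fa"])

  expect_error(species_mean_table(data.frame(clone_id = "zz", total_fa = 1,
                                             total_pufa = 1,
                                             total_omega3 = 1, epa = 1),
                                  clones), "unknown clone_id")
})

test_that("Kruskal-Wallis H matches the brute-force rank formula", {
  cases <- list(
    list(c(1, 2), c(3, 4), c(5, 6, 7, 8)),
    list(c(2.1, 9.9, 3.3), c(5.5, 0.1), c(4.4, 8.8, 7.7, 6.6)),
    list(c(1, 1, 2), c(2, 3, 3), c(4, 4, 1)),      # ties
    list(rnorm(8), rnorm(8) + 1)
  )
  set.seed(1)
  for (gr in cases) {
    kw <- kruskal_wallis(gr)
    expect_equal(kw$H, kw_oracle_h(gr), tolerance = 1e-12)
    expect_equal(kw$df, length(gr) - 1)
    expect_equal(kw$p_value,
                 stats::pchisq(kw$H, length(gr) - 1, lower.tail = FALSE))
  }

  # degenerate conventions
  expect_equal(kruskal_wallis(list(c(2, 2), c(2, 2)))$H, 0)
  expect_equal(kruskal_wallis(list(c(2, 2), c(2, 2)))$p_value, 1)
  ident <- kruskal_wallis(list(c(1, 2), c(1, 2)))
  expect_equal(ident$H, 0)
  expect_equal(ident$p_value, 1)
  expect_error(kruskal_wallis(list(1:3)), ">= 2")
})

test_that("Kruskal-Wallis is invariant under monotone transforms and null-calibrated", {
  set.seed(7)
  gr <- list(runif(6), runif(7), runif(5))
  h1 <- kruskal_wallis(gr)$H
  h2 <- kruskal_wallis(lapply(gr, function(x) exp(3 * x) - 1))$H
  expect_equal(h1, h2)

  # permuting labels of identically distributed data gives uniform p-values
  set.seed(42)
  pvals <- replicate(300, {
    kruskal_wallis(split(rnorm(24), rep(1:3, each = 8)))$p_value
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("species-level Kruskal-Wallis tests run per analyte", {
  clones <- default_config()$clones
  fa <- simulate_fattyacids(default_config(), seed = 6)
  neo <- fa[fa$stage == "neonate", ]
  neo <- cbind(neo["clone_id"], fa_totals(neo))
  kw <- kruskal_species_tests(neo, clones)
  expect_equal(kw$analyte, c("total_fa", "total_pufa", "total_omega3",
                             "epa"))
  expect_true(all(kw$df == 2))
  expect_true(all(kw$p_value >= 0 & kw$p_value <= 1))
  kw2 <- kruskal_species_tests(neo, clones, level = "sample")
  expect_true(all(is.finite(kw2$H)))
})
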