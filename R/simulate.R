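#' Default simulation configuration for the growth-experiment design
#'
#' Builds the configuration the synthetic-data generator uses to emulate the
#' study design: 12 clones of three species with body sizes from
#' [daphnia_clones()], 7 dietary EPA levels spanning 0--10 ug EPA mg C^-1,
#' 3 replicate beakers per treatment, and a 6-day experiment.  The true
#' half-saturation constants follow the linear size law K_S = K0 + K_L * L
#' with (K0, K_L) obtained by least squares from the bundled per-clone K_S
#' table ([ks_reference()]), so each clone's true K_S reproduces that table
#' within 0.005 ug EPA mg C^-1.  True baseline growth rates g0 are the
#' species-level anchors 0.174 (longispina complex), 0.312 (pulicaria) and
#' 0.432 (magna) day^-1; the true asymptote g_inf = 0.55 day^-1 is common to
#' all clones, so clone-level structure enters only through g0 and the size
#' law (a "B1-type" truth).
#'
#' @return An object of class `sim_config`: a list with entries `clones`,
#'   `epa_grid`, `n_replicates`, `duration_t`, `true_g0_by_clone`,
#'   `true_ginf_by_clone`, `true_K0`, `true_KL`, `random_effect_sd`
#'   (named sds for `g0`, `ginf`, `KS`), `residual_sd`, `seed`, plus
#'   clutch-size settings (`clutch_anchor_by_species`, `eggless_clones`,
#'   `clutch_sd`) and fatty-acid settings (`fa_sdlog`, `dwt_neonate`,
#'   `dwt_day6`, `dwt_sd`, `n_fa_replicates`).
#' @examples
#' cfg <- default_config()
#' cfg$true_K0 + cfg$true_KL * 1.77  # true K_S of clone Dg, ~0.60
#' @export
default_config <- function() {
  clones <- daphnia_clones()
  ref <- ks_reference()
  law <- size_law_from_ks(ref$ks, ref$body_size_L)
  g0_species <- c(longispina_complex = 0.174, pulicaria = 0.312,
                  magna = 0.432)
  cfg <- list(
    clones = clones,
    epa_grid = c(0, 0.5, 1, 2, 4, 7, 10),
    n_replicates = 3L,
    duration_t = 6,
    mass_W0 = 7.5,
    true_g0_by_clone = stats::setNames(g0_species[clones$species],
                                       clones$clone_id),
    true_ginf_by_clone = stats::setNames(rep(0.55, nrow(clones)),
                                         clones$clone_id),
    true_K0 = law$K0,
    true_KL = law$KL,
    random_effect_sd = c(g0 = 0.02, ginf = 0, KS = 0),
    residual_sd = 0.02,
    seed = 1L,
    clutch_anchor_by_species = c(longispina_complex = 1.31,
                                 pulicaria = 1.35, magna = 2.48),
    eggless_clones = c("Dg", "Dh"),
    clutch_disp = 0.25,
    fa_sdlog = 0.15,
    dwt_neonate = 489.55,
    dwt_day6 = 575.91,
    dwt_sd = 32.21,
    n_fa_replicates = 3L
  )
  structure(cfg, class = "sim_config")
}

#' Validate a simulation configuration
#'
#' @param config a `sim_config` list (see [default_config()]).
#' @return The config, invisibly; errors describe the violated invariant.
#' @export
validate_config <- function(config) {
  validate_clone_table(config$clones)
  if (any(diff(config$epa_grid) <= 0) || any(config$epa_grid < 0))
    stop("epa_grid must be non-negative and strictly increasing",
         call. = FALSE)
  if (config$n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  if (config$residual_sd < 0) stop("residual_sd must be >= 0", call. = FALSE)
  if (any(config$random_effect_sd < 0))
    stop("random_effect_sd values must be >= 0", call. = FALSE)
  ks <- config$true_K0 + config$true_KL * config$clones$body_size_L
  if (any(ks <= 0))
    stop("true size law gives non-positive KS for clone(s) ",
         paste(config$clones$clone_id[ks <= 0], collapse = ", "),
         call. = FALSE)
  miss <- setdiff(config$clones$clone_id, names(config$true_g0_by_clone))
  if (length(miss))
    stop("true_g0_by_clone missing clone(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible(config)
}

#' True clone-level Monod parameters implied by a configuration
#'
#' @param config a validated `sim_config`.
#' @return data.frame with `clone_id`, `species`, `body_size_L`, `g0`,
#'   `ginf`, `KS` (the deterministic anchors, before clone-level random
#'   deviations are drawn).
#' @export
true_clone_params <- function(config) {
  cl <- config$clones
  data.frame(
    clone_id = cl$clone_id,
    species = cl$species,
    body_size_L = cl$body_size_L,
    g0 = unname(config$true_g0_by_clone[cl$clone_id]),
    ginf = unname(config$true_ginf_by_clone[cl$clone_id]),
    KS = config$true_K0 + config$true_KL * cl$body_size_L,
    stringsAsFactors = FALSE
  )
}

# Draw clone-level Gaussian deviations for (g0, ginf, KS); the KS deviation
# is redrawn until the clone's total KS stays positive (truncation).
.draw_clone_deviations <- function(config, truth) {
  m <- nrow(truth)
  sd <- config$random_effect_sd
  dev <- cbind(g0 = stats::rnorm(m, 0, sd[["g0"]]),
               ginf = stats::rnorm(m, 0, sd[["ginf"]]),
               KS = stats::rnorm(m, 0, sd[["KS"]]))
  if (sd[["KS"]] > 0) {
    for (i in seq_len(m)) {
      tries <- 0
      while (truth$KS[i] + dev[i, "KS"] <= 1e-6 && tries < 1000) {
        dev[i, "KS"] <- stats::rnorm(1, 0, sd[["KS"]])
        tries <- tries + 1
      }
      if (truth$KS[i] + dev[i, "KS"] <= 1e-6)
        stop("cannot draw positive KS for clone ", truth$clone_id[i],
             call. = FALSE)
    }
  }
  dev
}

#' Simulate beaker-level juvenile growth observations
#'
#' One record per clone x EPA level x replicate.  Each observed growth rate
#' is the Monod-type mean for the clone's parameters (deterministic anchors
#' plus clone-level Gaussian deviations with the configured standard
#' deviations) plus Gaussian residual noise.  Initial dry mass is fixed at
#' `config$mass_W0` and the final mass is back-computed so that
#' `juvenile_growth_rate()` applied to the masses reproduces the stored
#' growth rate exactly.  Identical seed and config give bit-identical output.
#'
#' @param config a `sim_config` (see [default_config()]).
#' @param seed integer seed; defaults to `config$seed`.
#' @return data.frame in the growth-table schema (see
#'   [read_growth_table()]), with attribute `"clone_params"` holding the
#'   realised per-clone parameters.
#' @export
simulate_growth <- function(config = default_config(), seed = config$seed) {
  validate_config(config)
  truth <- true_clone_params(config)
  set.seed(seed)
  dev <- .draw_clone_deviations(config, truth)
  real <- truth
  real$g0 <- truth$g0 + dev[, "g0"]
  real$ginf <- truth$ginf + dev[, "ginf"]
  real$KS <- truth$KS + dev[, "KS"]

  grid <- expand.grid(replicate = seq_len(config$n_replicates),
                      epa_conc_S = config$epa_grid,
                      clone_id = truth$clone_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  i <- match(grid$clone_id, real$clone_id)
  mu <- real$g0[i] + (real$ginf[i] - real$g0[i]) *
    grid$epa_conc_S / (grid$epa_conc_S + real$KS[i])
  g <- mu + stats::rnorm(nrow(grid), 0, config$residual_sd)
  out <- data.frame(
    clone_id = grid$clone_id,
    epa_conc_S = grid$epa_conc_S,
    replicate = grid$replicate,
    growth_rate_g = g,
    mass_initial_W0 = config$mass_W0,
    mass_final_Wt = config$mass_W0 * exp(g * config$duration_t),
    duration_t = config$duration_t,
    stringsAsFactors = FALSE
  )
  attr(out, "clone_params") <- real
  out
}

#' Simulate clutch-size observations
#'
#' Clutch means follow a saturating Monod-type curve of dietary EPA,
#' c(S) = c_inf * S / (S + K_S), with the clone's K_S from the size law and
#' the asymptote c_inf chosen so the clone's mean clutch over the treatment
#' grid equals its species-level anchor (defaults 1.31 / 1.35 / 2.48 eggs
#' per female).  Clones listed in `config$eggless_clones` produce no eggs at
#' all.  Noise is Gaussian with a count-like mean-variance relation,
#' sd = `clutch_disp` * sqrt(mean), truncated at zero -- so residual scatter
#' grows with the mean, the heteroscedasticity the arcsine-square-root
#' transform is there to stabilise.
#'
#' @inheritParams simulate_growth
#' @return data.frame in the clutch-table schema, with attribute
#'   `"clutch_params"` (per-clone `c_inf` and `KS`).
#' @export
simulate_clutch <- function(config = default_config(), seed = config$seed) {
  validate_config(config)
  truth <- true_clone_params(config)
  set.seed(seed + 1L)
  grid_u <- function(ks) mean(config$epa_grid / (config$epa_grid + ks))
  anchors <- config$clutch_anchor_by_species[truth$species]
  cinf <- ifelse(truth$clone_id %in% config$eggless_clones, 0,
                 anchors / vapply(truth$KS, grid_u, numeric(1)))
  grid <- expand.grid(replicate = seq_len(config$n_replicates),
                      epa_conc_S = config$epa_grid,
                      clone_id = truth$clone_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  i <- match(grid$clone_id, truth$clone_id)
  mu <- cinf[i] * grid$epa_conc_S / (grid$epa_conc_S + truth$KS[i])
  c_obs <- mu
  if (config$clutch_disp > 0) {
    noise <- stats::rnorm(nrow(grid)) * config$clutch_disp * sqrt(mu)
    c_obs <- pmax(0, mu + noise)
  }
  out <- data.frame(
    clone_id = grid$clone_id,
    epa_conc_S = grid$epa_conc_S,
    replicate = grid$replicate,
    clutch_size_c = c_obs,
    stringsAsFactors = FALSE
  )
  attr(out, "clutch_params") <- data.frame(clone_id = truth$clone_id,
                                           c_inf = cinf, KS = truth$KS,
                                           stringsAsFactors = FALSE)
  out
}

# Decompose reference analyte totals into the five quantified FAME pools.
# ALA:ETE within (omega3 - EPA) uses a fixed 9:1 split; LIN = PUFA - omega3
# floored at zero (one printed row has omega3 marginally above PUFA).
.fame_centers <- function(ref) {
  lin <- pmax(0, ref$total_pufa - ref$total_omega3)
  rest <- pmax(0, ref$total_omega3 - ref$epa)
  data.frame(
    clone_id = ref$clone_id,
    lin_18_2w6 = lin,
    ala_18_3w3 = 0.9 * rest,
    ete_20_3w3 = 0.1 * rest,
    epa_20_5w3 = ref$epa,
    other_fa = pmax(0, ref$total_fa - (lin + rest + ref$epa)),
    stringsAsFactors = FALSE
  )
}

#' Simulate per-sample fatty-acid profiles
#'
#' Generates neonate and day-6 samples for the eight chemically analysed
#' clones.  Neonate per-FAME contents are centred on the bundled neonate
#' reference means ([fa_reference()]); day-6 contents are derived so that
#' the newly-built-biomass tissue quota computed from the clone-mean
#' profiles equals the bundled new-biomass reference values.  Multiplicative
#' lognormal noise (sdlog `config$fa_sdlog`, mean-preserving) is applied per
#' sample; dry masses are Gaussian around `config$dwt_neonate` /
#' `config$dwt_day6`.  Analytes that are missing in the reference (below
#' detection) stay `NA`.
#'
#' @inheritParams simulate_growth
#' @return data.frame in the fatty-acid-table schema (see
#'   [read_fattyacid_table()]).
#' @export
simulate_fattyacids <- function(config = default_config(),
                                seed = config$seed) {
  validate_config(config)
  set.seed(seed + 2L)
  neo_ref <- fa_reference("neonate")
  qta_ref <- fa_reference("new_biomass")
  keep <- neo_ref$clone_id %in% config$clones$clone_id
  if (!any(keep))
    stop("none of the configured clones is in the fatty-acid panel",
         call. = FALSE)
  neo_ref <- neo_ref[keep, , drop = FALSE]
  qta_ref <- qta_ref[keep, , drop = FALSE]
  c0 <- .fame_centers(neo_ref)
  qta <- .fame_centers(qta_ref)
  pufa_cols <- setdiff(.fame_cols, "other_fa")
  qta$lin_18_2w6[is.na(qta_ref$total_pufa)] <- NA
  qta$ala_18_3w3[is.na(qta_ref$total_omega3)] <- NA
  qta$ete_20_3w3[is.na(qta_ref$total_omega3)] <- NA
  qta$epa_20_5w3[is.na(qta_ref$epa)] <- NA
  m0 <- config$dwt_neonate
  m6 <- config$dwt_day6
  # invert the quota identity at the clone-mean level,
  # C6 = (q * (m6 - m0) + C0 * m0) / m6, per detected PUFA, then place the
  # remainder of the total-FA quota in the pooled non-PUFA pool (so the
  # total-FA quota is reproduced even where PUFAs were undetected)
  invert <- function(q, c0v) (q * (m6 - m0) + c0v * m0) / m6
  c6 <- c0
  for (col in pufa_cols) c6[[col]] <- invert(qta[[col]], c0[[col]])
  c0_fa_total <- rowSums(c0[.fame_cols])
  c6_fa_total <- invert(qta_ref$total_fa, c0_fa_total)
  c6$other_fa <- pmax(0, c6_fa_total -
                        rowSums(c6[pufa_cols], na.rm = TRUE))

  one_stage <- function(centers, stage, dwt_mean) {
    rows <- lapply(seq_len(nrow(centers)), function(i) {
      reps <- config$n_fa_replicates
      df <- data.frame(
        clone_id = centers$clone_id[i], stage = stage,
        replicate = seq_len(reps),
        dry_mass_ug = pmax(1, stats::rnorm(reps, dwt_mean, config$dwt_sd)),
        stringsAsFactors = FALSE
      )
      for (col in .fame_cols) {
        mu <- centers[[col]][i]
        noise <- stats::rnorm(reps, 0, 1)
        df[[col]] <- if (is.na(mu)) NA_real_ else if (config$fa_sdlog > 0)
          mu * exp(config$fa_sdlog * noise - config$fa_sdlog^2 / 2)
        else rep(mu, reps)
      }
      df
    })
    do.call(rbind, rows)
  }
  out <- rbind(one_stage(c0, "neonate", m0), one_stage(c6, "day6", m6))
  rownames(out) <- NULL
  attr(out, "centers") <- list(neonate = c0, day6 = c6)
  out
}

#' Write a complete simulated dataset to a directory
#'
#' Runs [simulate_growth()], [simulate_clutch()] and [simulate_fattyacids()]
#' under one seed and writes `growth.csv`, `clones.csv`, `clutch.csv` and
#' `fattyacids.csv`.
#'
#' @inheritParams simulate_growth
#' @param out_dir output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
simulate_dataset <- function(config = default_config(), seed = config$seed,
                             out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(growth = file.path(out_dir, "growth.csv"),
             clones = file.path(out_dir, "clones.csv"),
             clutch = file.path(out_dir, "clutch.csv"),
             fattyacids = file.path(out_dir, "fattyacids.csv"))
  write_growth_table(simulate_growth(config, seed), paths["growth"])
  write_clone_table(config$clones, paths["clones"])
  write_clutch_table(simulate_clutch(config, seed), paths["clutch"])
  write_fattyacid_table(simulate_fattyacids(config, seed),
                        paths["fattyacids"])
  invisible(paths)
}
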