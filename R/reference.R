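#' Reference panel of experimental Daphnia clones
#'
#' The twelve clonal lineages used in the EPA growth study this package
#' models: four clones each of the small-bodied *D. longispina* species
#' complex, the medium-bodied *D. pulicaria*, and the large-bodied
#' *D. magna*, with body size at first reproduction (mm, mean and standard
#' error over 8--15 individuals).
#'
#' @return A data.frame with columns `clone_id`, `species` (one of
#'   `"longispina_complex"`, `"pulicaria"`, `"magna"`), `body_size_L` (mm)
#'   and `body_size_se` (mm).
#' @examples
#' daphnia_clones()
#' @export
daphnia_clones <- function() {
  data.frame(
    clone_id = c("DlE", "Dl4", "Dh", "Dg",
                 "DpBrA3", "DpBrS", "DpGr8", "DpGr49",
                 "IL-M1-12", "IL-M1-8", "FI-N26-8c", "FI-N47-20"),
    species = rep(c("longispina_complex", "pulicaria", "magna"), each = 4),
    body_size_L = c(1.43, 1.49, 1.59, 1.77,
                    1.90, 2.09, 2.28, 2.31,
                    3.06, 3.18, 3.33, 3.54),
    body_size_se = c(0.02, 0.02, 0.02, 0.02,
                     0.01, 0.03, 0.04, 0.03,
                     0.02, 0.02, 0.09, 0.04),
    stringsAsFactors = FALSE
  )
}

#' Published half-saturation constants and 75% saturation thresholds
#'
#' Per-clone half-saturation constants K_S (ug EPA mg C^-1) for
#' EPA-dependent juvenile growth, as estimated with the size-dependent
#' mixed model (parametric point estimates plus residual-bootstrap
#' estimates and standard errors), together with the dietary EPA
#' concentration giving 75% of the asymptotic growth increment.
#' These printed values parameterise the synthetic-data generator and
#' serve as worked-example inputs for the threshold arithmetic.
#'
#' @return A data.frame with columns `clone_id`, `species`, `body_size_L`,
#'   `ks` and `ks_boot` (ug EPA mg C^-1), `ks_boot_se`, `s75`, `s75_boot`,
#'   `s75_boot_se`.
#' @seealso [saturation_threshold()], [size_law_from_ks()]
#' @export
ks_reference <- function() {
  cl <- daphnia_clones()
  data.frame(
    clone_id = cl$clone_id,
    species = cl$species,
    body_size_L = cl$body_size_L,
    ks       = c(0.25, 0.31, 0.41, 0.60, 0.74, 0.93, 1.13, 1.16,
                 1.94, 2.07, 2.22, 2.44),
    ks_boot  = c(0.39, 0.45, 0.55, 0.74, 0.87, 1.06, 1.26, 1.29,
                 2.06, 2.18, 2.33, 2.55),
    ks_boot_se = c(0.50, 0.48, 0.46, 0.46, 0.49, 0.57, 0.68, 0.70,
                   1.25, 1.34, 1.46, 1.63),
    s75      = c(0.74, 0.93, 1.24, 1.80, 2.21, 2.80, 3.39, 3.49,
                 5.83, 6.21, 6.67, 7.33),
    s75_boot = c(1.17, 1.35, 1.66, 2.21, 2.61, 3.19, 3.77, 3.87,
                 6.53, 6.99, 7.64, 7.48),
    s75_boot_se = c(1.51, 1.45, 1.39, 1.39, 1.48, 1.72, 2.04, 2.10,
                    3.74, 4.02, 4.38, 4.89),
    stringsAsFactors = FALSE
  )
}

#' Reference fatty-acid contents of neonates and of newly built biomass
#'
#' Clone-level mean fatty-acid contents (ng ug^-1 dry weight) for the eight
#' clones analysed chemically: total fatty acids, total polyunsaturated
#' fatty acids (PUFA = LIN 18:2w6 + ALA 18:3w3 + ETE 20:3w3 + EPA 20:5w3),
#' total omega-3 PUFA (ALA + ETE + EPA) and EPA itself.  `stage = "neonate"`
#' gives contents of <18 h old animals; `stage = "new_biomass"` gives the
#' minimum tissue quota of biomass newly built over six days of growth at
#' 75% EPA saturation.  Cells that were below detection are `NA`.
#'
#' @param stage `"neonate"` or `"new_biomass"`.
#' @return A data.frame with columns `clone_id`, `species`, `total_fa`,
#'   `total_pufa`, `total_omega3`, `epa` and matching `*_se` columns
#'   (all ng ug^-1 dwt).
#' @export
fa_reference <- function(stage = c("neonate", "new_biomass")) {
  stage <- match.arg(stage)
  clones <- c("DlE", "Dl4", "DpBrS", "DpBrA3",
              "IL-M1-12", "IL-M1-8", "FI-N26-8c", "FI-N47-20")
  species <- c("longispina_complex", "longispina_complex",
               "pulicaria", "pulicaria", rep("magna", 4))
  if (stage == "neonate") {
    out <- data.frame(
      clone_id = clones, species = species,
      total_fa     = c(47.36, 35.80, 37.42, 43.35, 37.76, 37.26, 50.16, 14.81),
      total_fa_se  = c(5.96, 7.85, 8.23, 17.39, 1.94, 5.85, 7.15, 8.27),
      total_pufa   = c(25.53, 19.24, 14.91, 9.76, 20.35, 17.52, 29.68, 5.99),
      total_pufa_se = c(4.13, 6.50, 5.01, 3.27, 1.40, 1.88, 4.61, 3.94),
      total_omega3 = c(24.81, 17.79, 13.48, 8.88, 18.89, 16.11, 27.97, 5.32),
      total_omega3_se = c(3.52, 6.24, 4.80, 3.07, 1.36, 1.84, 4.47, 3.60),
      epa          = c(1.55, 0.36, 0.06, 0.38, 0.34, 0.11, 0.23, 0.35),
      epa_se       = c(0.24, 0.24, 0.03, 0.13, 0.00, 0.04, 0.07, 0.06),
      stringsAsFactors = FALSE
    )
  } else {
    out <- data.frame(
      clone_id = clones, species = species,
      total_fa     = c(9.23, 52.56, 79.46, 99.55, 27.51, 47.99, 69.43, 64.28),
      total_fa_se  = c(0.00, 33.68, 11.30, 8.48, 6.28, 13.08, 5.44, 3.37),
      total_pufa   = c(NA, 5.53, 0.96, 2.59, 1.71, 2.45, 2.64, 2.21),
      total_pufa_se = c(NA, 3.92, 0.21, 0.58, 0.09, 0.78, 1.44, 0.04),
      total_omega3 = c(NA, 5.03, 1.01, 2.20, 1.34, 2.08, 1.42, 1.82),
      total_omega3_se = c(NA, 3.65, 0.22, 0.57, 0.05, 0.74, 0.95, 0.05),
      epa          = c(NA, 0.78, 0.25, 0.16, 0.86, 1.22, 1.86, 0.24),
      epa_se       = c(NA, 0.30, 0.12, 0.02, 0.18, 0.50, 1.16, 0.07),
      stringsAsFactors = FALSE
    )
  }
  out
}

#' Body-size law underlying a table of half-saturation constants
#'
#' Ordinary least squares of per-clone half-saturation constants on body
#' size at first reproduction, returning the intercept K0 and slope K_L of
#' the linear size law K_S = K0 + K_L * L.  Applied to [ks_reference()]
#' this recovers the size law used to generate synthetic data.
#'
#' @param ks numeric vector of half-saturation constants (ug EPA mg C^-1).
#' @param L numeric vector of body sizes (mm), same length.
#' @return A list with elements `K0`, `KL`, `fitted`, `residuals` and
#'   `max_abs_residual`.
#' @examples
#' ref <- ks_reference()
#' size_law_from_ks(ref$ks, ref$body_size_L)
#' @export
size_law_from_ks <- function(ks, L) {
  stopifnot(length(ks) == length(L), length(ks) >= 2)
  fit <- stats::lm(ks ~ L)
  co <- stats::coef(fit)
  list(K0 = unname(co[1]), KL = unname(co[2]),
       fitted = unname(stats::fitted(fit)),
       residuals = unname(stats::resid(fit)),
       max_abs_residual = max(abs(stats::resid(fit))))
}
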