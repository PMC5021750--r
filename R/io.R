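# Tidy-CSV interchange: one header row, UTF-8, "." decimal separator.
# Units are fixed throughout (day^-1, ug EPA mg C^-1, mm, ng ug^-1 dwt);
# no unit auto-conversion is performed anywhere.

.growth_cols <- c("clone_id", "epa_conc_S", "replicate", "growth_rate_g",
                  "mass_initial_W0", "mass_final_Wt", "duration_t")
.clone_cols <- c("clone_id", "species", "body_size_L", "body_size_se")
.clutch_cols <- c("clone_id", "epa_conc_S", "replicate", "clutch_size_c")
.fame_cols <- c("lin_18_2w6", "ala_18_3w3", "ete_20_3w3", "epa_20_5w3",
                "other_fa")
.fa_cols <- c("clone_id", "stage", "replicate", "dry_mass_ug", .fame_cols)

.species_levels <- c("longispina_complex", "pulicaria", "magna")

.read_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

.check_schema <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s: missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

.fail_rows <- function(bad, msg, what) {
  if (any(bad, na.rm = TRUE))
    stop(sprintf("%s: %s in row(s) %s", what, msg,
                 paste(which(bad), collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

#' Validate a clone table
#'
#' @param clones data.frame with columns `clone_id`, `species`,
#'   `body_size_L`, `body_size_se`.
#' @return The validated data.frame, invisibly unchanged.
#' @export
validate_clone_table <- function(clones) {
  .check_schema(clones, .clone_cols, "clone table")
  .fail_rows(duplicated(clones$clone_id), "duplicated clone_id", "clone table")
  .fail_rows(!(clones$species %in% .species_levels),
             paste("species not one of",
                   paste(.species_levels, collapse = "/")), "clone table")
  .fail_rows(!is.finite(clones$body_size_L) | clones$body_size_L <= 0,
             "non-positive body_size_L", "clone table")
  invisible(clones)
}

#' Validate growth records against a clone table
#'
#' Checks the beaker-level growth schema: non-negative EPA concentration,
#' positive duration, positive masses where present, at least one of
#' `growth_rate_g` or the (`mass_initial_W0`, `mass_final_Wt`) pair per row,
#' and `clone_id` values known to the clone table.
#'
#' @param records growth data.frame (see [read_growth_table()]).
#' @param clones validated clone table.
#' @return The records, invisibly, with `growth_rate_g` filled in from the
#'   masses where it was missing.
#' @export
validate_growth_records <- function(records, clones) {
  .check_schema(records, .growth_cols, "growth table")
  what <- "growth table"
  .fail_rows(!(records$clone_id %in% clones$clone_id), "unknown clone_id", what)
  .fail_rows(!is.finite(records$epa_conc_S) | records$epa_conc_S < 0,
             "negative or missing epa_conc_S", what)
  .fail_rows(!is.finite(records$duration_t) | records$duration_t <= 0,
             "non-positive duration_t", what)
  .fail_rows(is.na(records$replicate) | records$replicate < 1,
             "replicate must be a positive integer", what)
  has_mass <- !is.na(records$mass_initial_W0) & !is.na(records$mass_final_Wt)
  .fail_rows(has_mass & (records$mass_initial_W0 <= 0 |
                           records$mass_final_Wt <= 0),
             "non-positive dry mass", what)
  .fail_rows(is.na(records$growth_rate_g) & !has_mass,
             "neither growth_rate_g nor both masses present", what)
  fill <- is.na(records$growth_rate_g) & has_mass
  if (any(fill))
    records$growth_rate_g[fill] <- juvenile_growth_rate(
      records$mass_initial_W0[fill], records$mass_final_Wt[fill],
      records$duration_t[fill])
  invisible(records)
}

#' Read a growth table and its clone table from CSV
#'
#' @param path path to the growth CSV (columns `clone_id`, `epa_conc_S`,
#'   `replicate`, `growth_rate_g`, `mass_initial_W0`, `mass_final_Wt`,
#'   `duration_t`; the mass columns may be empty when `growth_rate_g` is
#'   given, and vice versa).
#' @param clone_table path to the clone CSV (columns `clone_id`, `species`,
#'   `body_size_L`, `body_size_se`).
#' @return A list with elements `growth` (validated records, growth rate
#'   filled in from masses where needed) and `clones`.
#' @export
read_growth_table <- function(path, clone_table) {
  clones <- validate_clone_table(.read_csv(clone_table))
  records <- .read_csv(path)
  records <- validate_growth_records(records, clones)
  list(growth = records, clones = clones)
}

#' Write a growth table (and companions) to CSV
#'
#' `write_growth_table()`, `write_clone_table()`, `write_clutch_table()` and
#' `write_fattyacid_table()` write the corresponding tidy schemas; paired
#' with the readers they are exact round-trips.
#'
#' @param records data.frame in the corresponding schema.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_growth_table <- function(records, path) {
  .check_schema(records, .growth_cols, "growth table")
  utils::write.csv(records[, .growth_cols], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_growth_table
#' @export
write_clone_table <- function(records, path) {
  .check_schema(records, .clone_cols, "clone table")
  utils::write.csv(records[, .clone_cols], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_growth_table
#' @export
write_clutch_table <- function(records, path) {
  .check_schema(records, .clutch_cols, "clutch table")
  utils::write.csv(records[, .clutch_cols], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_growth_table
#' @export
write_fattyacid_table <- function(records, path) {
  .check_schema(records, .fa_cols, "fatty-acid table")
  utils::write.csv(records[, .fa_cols], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a clutch-size table from CSV
#'
#' @param path clutch CSV (columns `clone_id`, `epa_conc_S`, `replicate`,
#'   `clutch_size_c`).
#' @param clones validated clone table (data.frame).
#' @return Validated clutch records.
#' @export
read_clutch_table <- function(path, clones) {
  records <- .read_csv(path)
  .check_schema(records, .clutch_cols, "clutch table")
  what <- "clutch table"
  .fail_rows(!(records$clone_id %in% clones$clone_id), "unknown clone_id", what)
  .fail_rows(!is.finite(records$epa_conc_S) | records$epa_conc_S < 0,
             "negative or missing epa_conc_S", what)
  .fail_rows(!is.finite(records$clutch_size_c) | records$clutch_size_c < 0,
             "negative clutch_size_c", what)
  records
}

#' Read a fatty-acid sample table from CSV
#'
#' Wide per-sample schema: one row per analysed sample with the dry mass and
#' the quantified FAME contents (ng ug^-1 dwt): linoleic acid 18:2w6,
#' alpha-linolenic acid 18:3w3, eicosatrienoic acid 20:3w3, EPA 20:5w3, and
#' the pooled non-PUFA fatty acids. `NA` cells mean "not detected" and
#' propagate as missing.
#'
#' @param path fatty-acid CSV.
#' @param clones validated clone table.
#' @return Validated fatty-acid sample records.
#' @export
read_fattyacid_table <- function(path, clones) {
  records <- .read_csv(path)
  .check_schema(records, .fa_cols, "fatty-acid table")
  what <- "fatty-acid table"
  .fail_rows(!(records$clone_id %in% clones$clone_id), "unknown clone_id", what)
  .fail_rows(!(records$stage %in% c("neonate", "day6")),
             "stage must be 'neonate' or 'day6'", what)
  .fail_rows(!is.finite(records$dry_mass_ug) | records$dry_mass_ug <= 0,
             "non-positive dry_mass_ug", what)
  for (col in .fame_cols)
    .fail_rows(!is.na(records[[col]]) & records[[col]] < 0,
               paste("negative", col), what)
  records
}

#' Write a model fit to a machine-readable JSON report
#'
#' Stores the model name, fixed-effect estimates, random-effect and residual
#' standard deviations, clone-level deviations, log-likelihood, degrees of
#' freedom, AIC, convergence flag, and any attached bootstrap standard
#' errors, at full floating-point precision.
#'
#' @param fit a `monod_fit` object from [fit_nlme()].
#' @param path output path (`.json`).
#' @return `path`, invisibly.
#' @seealso [read_fit_report()]
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "monod_fit"))
  rpt <- list(
    model = fit$spec$name,
    family = fit$spec$family,
    random_set = fit$spec$random_set,
    converged = isTRUE(fit$converged),
    fixed_estimates = as.list(fit$fixed_estimates),
    random_sd = as.list(fit$random_sd),
    residual_sd = fit$residual_sd,
    clone_deviations = fit$clone_deviations,
    logLik = fit$logLik,
    Df = fit$Df,
    AIC = fit$AIC,
    se = if (!is.null(fit$se)) as.list(fit$se)
  )
  jsonlite::write_json(rpt, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Re-read a JSON fit report
#'
#' @param path path written by [write_fit_report()].
#' @return A list mirroring the stored report (estimates as named numeric
#'   vectors, `clone_deviations` as a data.frame).
#' @export
read_fit_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  rpt <- jsonlite::read_json(path, simplifyVector = TRUE)
  rpt$fixed_estimates <- unlist(rpt$fixed_estimates)
  rpt$random_sd <- unlist(rpt$random_sd)
  rpt
}
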