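.analytes <- c("total_fa", "total_pufa", "total_omega3", "epa")

#' Fatty-acid totals of a sample profile
#'
#' Total PUFA is the sum of linoleic acid (18:2w6), alpha-linolenic acid
#' (18:3w3), eicosatrienoic acid (20:3w3) and EPA (20:5w3); total omega-3
#' excludes linoleic acid; total FA adds the pooled non-PUFA fatty acids.
#' `NA` contents (below detection) propagate to the affected totals.
#'
#' @param profile a data.frame (or single row) with columns `lin_18_2w6`,
#'   `ala_18_3w3`, `ete_20_3w3`, `epa_20_5w3`, `other_fa`
#'   (ng ug^-1 dwt).
#' @return A data.frame with columns `total_fa`, `total_pufa`,
#'   `total_omega3`, `epa`, one row per input row.  `total_fa` counts
#'   undetected (`NA`) components as zero (matching how a total is reported
#'   when individual PUFAs fall below detection); the PUFA totals stay `NA`
#'   when any of their components is undetected.
#' @examples
#' fa_totals(data.frame(lin_18_2w6 = 1, ala_18_3w3 = 2, ete_20_3w3 = 3,
#'                      epa_20_5w3 = 4, other_fa = 5))
#' @export
fa_totals <- function(profile) {
  need <- c("lin_18_2w6", "ala_18_3w3", "ete_20_3w3", "epa_20_5w3",
            "other_fa")
  miss <- setdiff(need, names(profile))
  if (length(miss))
    stop("profile missing FAME column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  omega3 <- profile$ala_18_3w3 + profile$ete_20_3w3 + profile$epa_20_5w3
  pufa <- profile$lin_18_2w6 + omega3
  comp <- cbind(profile$lin_18_2w6, profile$ala_18_3w3, profile$ete_20_3w3,
                profile$epa_20_5w3, profile$other_fa)
  total_fa <- rowSums(comp, na.rm = TRUE)
  total_fa[rowSums(!is.na(comp)) == 0] <- NA_real_
  data.frame(total_fa = total_fa,
             total_pufa = pufa,
             total_omega3 = omega3,
             epa = profile$epa_20_5w3)
}

#' Analyte content of newly built biomass (minimum tissue quota)
#'
#' The content of an analyte in the biomass gained between the neonate
#' stage and day 6: (C6 * m6 - C0 * m0) / (m6 - m0), where C is per-dry-mass
#' content and m is dry mass.  A negative result (net analyte loss despite
#' mass gain) is reported with `depleted = TRUE`, never clamped.  The
#' computation is invariant to rescaling both masses by a common factor.
#'
#' @param neonate,day6 lists or one-row data.frames for the same clone with
#'   `dry_mass_ug` and the FAME columns of [fa_totals()] (or precomputed
#'   analyte totals).
#' @param analyte one of `"total_fa"`, `"total_pufa"`, `"total_omega3"`,
#'   `"epa"`.
#' @return A list with `clone_id`, `analyte`, `content_new_biomass`
#'   (ng ug^-1 dwt) and `depleted`.
#' @export
newly_built_biomass_content <- function(neonate, day6,
                                        analyte = c("total_fa",
                                                    "total_pufa",
                                                    "total_omega3", "epa")) {
  analyte <- match.arg(analyte)
  if (!is.null(neonate$clone_id) && !is.null(day6$clone_id) &&
      !identical(as.character(neonate$clone_id),
                 as.character(day6$clone_id)))
    stop("neonate and day-6 profiles belong to different clones",
         call. = FALSE)
  m0 <- neonate$dry_mass_ug; m6 <- day6$dry_mass_ug
  if (!is.finite(m0) || !is.finite(m6) || m6 <= m0)
    stop("no growth: day-6 dry mass must exceed neonate dry mass",
         call. = FALSE)
  get_content <- function(p) {
    if (!is.null(p[[analyte]])) p[[analyte]]
    else fa_totals(as.data.frame(p))[[analyte]]
  }
  c0 <- get_content(neonate); c6 <- get_content(day6)
  q <- (c6 * m6 - c0 * m0) / (m6 - m0)
  list(clone_id = if (!is.null(neonate$clone_id))
         as.character(neonate$clone_id) else NA_character_,
       analyte = analyte,
       content_new_biomass = q,
       depleted = is.finite(q) && q < 0)
}

#' Per-clone tissue quotas from a fatty-acid sample table
#'
#' Averages the sample profiles within clone and stage, then computes the
#' newly-built-biomass content of each analyte from the clone-mean neonate
#' and day-6 profiles.
#'
#' @param fa_records fatty-acid sample table (see [read_fattyacid_table()]).
#' @return data.frame with one row per clone: `clone_id`, dry masses, and
#'   the four analyte quotas (`NA` where an analyte was undetected).
#' @export
tissue_quota_table <- function(fa_records) {
  clones <- unique(fa_records$clone_id)
  rows <- lapply(clones, function(cl) {
    mean_profile <- function(stage) {
      sub <- fa_records[fa_records$clone_id == cl &
                          fa_records$stage == stage, , drop = FALSE]
      if (!nrow(sub)) return(NULL)
      out <- as.list(colMeans(sub[, c("dry_mass_ug", .fame_cols)]))
      out$clone_id <- cl
      out
    }
    p0 <- mean_profile("neonate"); p6 <- mean_profile("day6")
    if (is.null(p0) || is.null(p6)) return(NULL)
    res <- list(clone_id = cl, dry_mass_neonate = p0$dry_mass_ug,
                dry_mass_day6 = p6$dry_mass_ug)
    for (a in .analytes) {
      q <- tryCatch(
        newly_built_biomass_content(p0, p6, a)$content_new_biomass,
        error = function(e) NA_real_)
      res[[a]] <- q
    }
    as.data.frame(res, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Species-level means of clone means
#'
#' Aggregates clone-level values to species level: samples are first
#' averaged within clone, then clone means are averaged within species
#' without replicate weighting; the SE is the standard deviation of the
#' clone means divided by the square root of the number of clones.  Missing
#' clone values (undetected analytes) are excluded with the divisor reduced;
#' a species with a single contributing clone gets `SE = NA`; a species with
#' none is omitted with a warning.
#'
#' @param data data.frame with `clone_id` and the value columns (sample- or
#'   clone-level rows).
#' @param clones clone table mapping `clone_id` to `species`.
#' @param values names of the value columns to aggregate; defaults to the
#'   four analyte totals.
#' @return data.frame with one row per species x analyte: `species`,
#'   `analyte`, `mean`, `se`, `n_clones`.
#' @export
species_mean_table <- function(data, clones,
                               values = .analytes) {
  miss <- setdiff(values, names(data))
  if (length(miss))
    stop("data missing value column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  sp <- clones$species[match(data$clone_id, clones$clone_id)]
  if (anyNA(sp))
    stop("unknown clone_id(s): ",
         paste(unique(data$clone_id[is.na(sp)]), collapse = ", "),
         call. = FALSE)
  # clone means first
  agg <- stats::aggregate(data[values], by = list(clone_id = data$clone_id),
                          FUN = mean, na.rm = FALSE)
  agg$species <- clones$species[match(agg$clone_id, clones$clone_id)]
  rows <- list()
  for (s in unique(clones$species[clones$clone_id %in% agg$clone_id])) {
    sub <- agg[agg$species == s, , drop = FALSE]
    for (v in values) {
      x <- sub[[v]][!is.na(sub[[v]])]
      k <- length(x)
      if (k == 0) {
        warning("species ", s, " has no clone values for ", v,
                call. = FALSE)
        next
      }
      rows[[length(rows) + 1]] <- data.frame(
        species = s, analyte = v, mean = mean(x),
        se = if (k > 1) stats::sd(x) / sqrt(k) else NA_real_,
        n_clones = k, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected Kruskal-Wallis one-way analysis of variance by ranks
#' (via [stats::kruskal.test()]), with the documented convention that a
#' completely degenerate input (all values identical) returns H = 0,
#' p = 1 instead of an error.
#'
#' @param groups list of at least two numeric vectors.
#' @return A list with `H`, `df` and `p_value`.
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6, 7, 8)))
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need a list of >= 2 groups", call. = FALSE)
  groups <- lapply(groups, function(g) g[!is.na(g)])
  groups <- groups[vapply(groups, length, integer(1)) > 0]
  if (length(groups) < 2)
    stop("need >= 2 non-empty groups", call. = FALSE)
  x <- unlist(groups)
  if (length(unique(x)) < 2)
    return(list(H = 0, df = length(groups) - 1L, p_value = 1))
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' Species comparison of fatty-acid analytes
#'
#' Runs the Kruskal-Wallis test of a species effect for each analyte, on
#' clone means (default, matching the species-level aggregation) or on
#' individual samples.
#'
#' @param data data.frame with `clone_id` and analyte columns.
#' @param clones clone table.
#' @param values analyte columns to test.
#' @param level `"clone"` (test clone means grouped by species) or
#'   `"sample"` (pool individual samples).
#' @return data.frame with `analyte`, `H`, `df`, `p_value`.
#' @export
kruskal_species_tests <- function(data, clones, values = .analytes,
                                  level = c("clone", "sample")) {
  level <- match.arg(level)
  if (level == "clone") {
    data <- stats::aggregate(data[values],
                             by = list(clone_id = data$clone_id),
                             FUN = mean, na.rm = FALSE)
  }
  sp <- clones$species[match(data$clone_id, clones$clone_id)]
  out <- lapply(values, function(v) {
    groups <- split(data[[v]][!is.na(data[[v]])], sp[!is.na(data[[v]])])
    groups <- groups[vapply(groups, length, integer(1)) > 0]
    if (length(groups) < 2)
      return(data.frame(analyte = v, H = NA_real_, df = NA_integer_,
                        p_value = NA_real_, stringsAsFactors = FALSE))
    kw <- kruskal_wallis(groups)
    data.frame(analyte = v, H = kw$H, df = kw$df, p_value = kw$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
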