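#' Akaike information criterion from log-likelihood and degrees of freedom
#'
#' AIC = 2 * Df - 2 * logLik, with Df counting fixed effects,
#' random-effect variance components and the residual variance.
#'
#' @param logLik maximised log-likelihood.
#' @param Df number of estimated parameters.
#' @return The AIC value.
#' @examples
#' aic(567.8, 6)  # -1123.6
#' @export
aic <- function(logLik, Df) 2 * Df - 2 * logLik

#' Pairwise likelihood-ratio test between nested A/B model fits
#'
#' Tests a family-A fit (common or randomly varying half-saturation
#' constant) against the family-B fit with the same random-effect set,
#' which nests it through K_L = 0.  The statistic is
#' chisq = 2 * (logLik_B - logLik_A), floored at zero, compared to a
#' chi-square distribution with Df_B - Df_A degrees of freedom.
#'
#' @param fit_null the family-A (null) `monod_fit`.
#' @param fit_alt the family-B (alternative) `monod_fit` with the same
#'   random-effect set.
#' @return A list with `chisq`, `chi_df` and `p_value`.
#' @export
lr_test <- function(fit_null, fit_alt) {
  sn <- fit_null$spec; sa <- fit_alt$spec
  if (!is.null(sn) && !is.null(sa)) {
    if (!(sn$family == "A" && sa$family == "B" &&
          identical(sn$random_set, sa$random_set)))
      stop(sprintf("models %s and %s are not a nested A/B pair",
                   sn$name, sa$name), call. = FALSE)
  }
  if (!isTRUE(fit_null$converged) || !isTRUE(fit_alt$converged))
    stop("both fits must have converged", call. = FALSE)
  chisq <- max(0, 2 * (fit_alt$logLik - fit_null$logLik))
  chi_df <- fit_alt$Df - fit_null$Df
  list(chisq = chisq, chi_df = chi_df,
       p_value = stats::pchisq(chisq, chi_df, lower.tail = FALSE))
}

#' Fit and rank the six-model A/B series
#'
#' Fits models A1, A2, A3, B1, B2, B3 (see [model_spec()]) to the growth
#' data, tabulates Df, AIC and logLik, runs the pairwise likelihood-ratio
#' test for each (A_k, B_k) pair, and selects the minimum-AIC model among
#' the converged fits (ties broken towards fewer Df).
#'
#' @param records growth table.
#' @param clones clone table.
#' @param models model names to fit; default the full series.
#' @param control passed to [fit_nlme()].
#' @return An object of class `selection_table`: list with `table`
#'   (one row per model), `pairwise_tests`, `best_model` and `fits`.
#' @export
run_model_series <- function(records, clones,
                             models = c("A1", "A2", "A3",
                                        "B1", "B2", "B3"),
                             control = list()) {
  fits <- lapply(models, function(m)
    tryCatch(fit_nlme(records, clones, m, control),
             error = function(e) structure(
               list(spec = model_spec(m), converged = FALSE,
                    message = conditionMessage(e)),
               class = "monod_fit")))
  names(fits) <- models
  tab <- do.call(rbind, lapply(fits, function(f) {
    conv <- isTRUE(f$converged)
    data.frame(
      model = f$spec$name,
      fixed_effects = if (f$spec$family == "A") "g0, ginf, KS"
                      else "g0, ginf, K0, KL",
      random_effects = paste(f$spec$random_set, collapse = ", "),
      Df = if (!is.null(f$Df)) f$Df else NA_integer_,
      AIC = if (conv) f$AIC else NA_real_,
      logLik = if (conv) f$logLik else NA_real_,
      converged = conv,
      stringsAsFactors = FALSE
    )
  }))
  rownames(tab) <- NULL
  ks <- intersect(1:3, as.integer(substr(models, 2, 2)))
  tests <- do.call(rbind, lapply(ks, function(k) {
    a <- fits[[paste0("A", k)]]; b <- fits[[paste0("B", k)]]
    if (is.null(a) || is.null(b) ||
        !isTRUE(a$converged) || !isTRUE(b$converged)) return(NULL)
    lt <- lr_test(a, b)
    data.frame(null_model = paste0("A", k), alt_model = paste0("B", k),
               chisq = lt$chisq, chi_df = lt$chi_df,
               p_value = lt$p_value, stringsAsFactors = FALSE)
  }))
  ok <- tab$converged & is.finite(tab$AIC)
  best <- NA_character_
  if (any(ok)) {
    cand <- tab[ok, ]
    cand <- cand[order(cand$AIC, cand$Df), ]
    best <- cand$model[1]
  }
  structure(list(table = tab, pairwise_tests = tests,
                 best_model = best, fits = fits),
            class = "selection_table")
}

#' @export
print.selection_table <- function(x, ...) {
  cat("Model selection across the A/B Monod mixed-model series\n\n")
  tab <- x$table
  tab$AIC <- round(tab$AIC, 1)
  tab$logLik <- round(tab$logLik, 1)
  print(tab, row.names = FALSE)
  if (!is.null(x$pairwise_tests) && nrow(x$pairwise_tests)) {
    cat("\nPairwise likelihood-ratio tests (A_k vs B_k):\n")
    pt <- x$pairwise_tests
    pt$chisq <- round(pt$chisq, 2)
    pt$p_value <- round(pt$p_value, 3)
    print(pt, row.names = FALSE)
  }
  cat("\nBest model (min AIC):", x$best_model, "\n")
  invisible(x)
}

#' Residual-bootstrap standard errors for K_S and saturation thresholds
#'
#' Resamples centred, variance-rescaled conditional residuals with
#' replacement at the observation level (pooled across clones), adds them
#' to the fitted values, refits the same model spec, and collects each
#' clone's half-saturation constant K_S and 75% saturation threshold
#' S75 = 3 * K_S.  Standard errors are the standard deviations across
#' replicates; 2.5% / 97.5% percentile intervals are reported alongside.
#' Deterministic given `seed`.
#'
#' @param fit a converged `monod_fit`.
#' @param n_boot number of bootstrap replicates (>= 2; default 1000).
#' @param seed integer seed.
#' @param refit_variance if `TRUE` (default) each replicate re-estimates
#'   the variance components; if `FALSE` they are fixed at the point
#'   estimates and only fixed effects are re-optimised.
#' @param control passed to the refits.
#' @return An object of class `bootstrap_summary`: list with `n_boot`,
#'   `n_dropped` (non-converged replicates, at most 20% tolerated), `seed`,
#'   and `summary` -- one row per clone with point estimates, bootstrap
#'   means, SEs and percentile intervals for K_S and S75.
#' @export
residual_bootstrap <- function(fit, n_boot = 1000, seed = 1,
                               refit_variance = TRUE, control = list()) {
  stopifnot(inherits(fit, "monod_fit"))
  if (!isTRUE(fit$converged)) stop("fit must have converged", call. = FALSE)
  if (n_boot < 2) stop("n_boot must be >= 2", call. = FALSE)
  prep <- fit$prep
  e <- fit$residuals - mean(fit$residuals)
  e <- e * sqrt(prep$n / max(1, prep$n - fit$Df))
  spec <- fit$spec
  clones <- data.frame(clone_id = prep$clone_id,
                       species = "magna",
                       body_size_L = prep$L,
                       body_size_se = 0,
                       stringsAsFactors = FALSE)
  obs_clone <- obs_S <- rep(NA_character_, prep$n)
  obs_clone[prep$ord] <- prep$clone_id[prep$idx]
  obs_S <- numeric(prep$n); obs_S[prep$ord] <- prep$S
  base <- data.frame(clone_id = obs_clone,
                     epa_conc_S = obs_S,
                     replicate = stats::ave(obs_S, obs_clone, obs_S,
                                            FUN = seq_along),
                     growth_rate_g = NA_real_,
                     mass_initial_W0 = NA_real_,
                     mass_final_Wt = NA_real_,
                     duration_t = 1,
                     stringsAsFactors = FALSE)
  ctrl <- utils::modifyList(list(restarts = 1), control)
  set.seed(seed)
  draws <- matrix(sample.int(prep$n, prep$n * n_boot, replace = TRUE),
                  nrow = prep$n)
  ks_mat <- matrix(NA_real_, n_boot, prep$m,
                   dimnames = list(NULL, prep$clone_id))
  fx_mat <- matrix(NA_real_, n_boot, length(fit$fixed_estimates),
                   dimnames = list(NULL, names(fit$fixed_estimates)))
  for (r in seq_len(n_boot)) {
    dat <- base
    dat$growth_rate_g <- fit$fitted + e[draws[, r]]
    bf <- tryCatch({
      if (refit_variance) fit_nlme(dat, clones, spec, ctrl)
      else .refit_fixed_only(dat, clones, fit)
    }, error = function(err) NULL)
    if (!is.null(bf) && isTRUE(bf$converged)) {
      ks_mat[r, ] <- bf$clone_params$KS
      fx_mat[r, ] <- bf$fixed_estimates
    }
  }
  ok <- stats::complete.cases(ks_mat)
  n_dropped <- sum(!ok)
  if (n_dropped > 0.2 * n_boot)
    stop(sprintf("%d of %d bootstrap replicates failed to converge",
                 n_dropped, n_boot), call. = FALSE)
  ks_mat <- ks_mat[ok, , drop = FALSE]
  qs <- function(x, p) unname(stats::quantile(x, p, type = 7))
  summ <- data.frame(
    clone_id = prep$clone_id,
    body_size_L = prep$L,
    ks = fit$clone_params$KS,
    ks_boot = colMeans(ks_mat),
    ks_se = apply(ks_mat, 2, stats::sd),
    ks_lo = apply(ks_mat, 2, qs, 0.025),
    ks_hi = apply(ks_mat, 2, qs, 0.975),
    stringsAsFactors = FALSE
  )
  summ$s75 <- 3 * summ$ks
  summ$s75_boot <- 3 * summ$ks_boot
  summ$s75_se <- 3 * summ$ks_se
  summ$s75_lo <- 3 * summ$ks_lo
  summ$s75_hi <- 3 * summ$ks_hi
  fx_mat <- fx_mat[ok, , drop = FALSE]
  fixed <- data.frame(
    parameter = names(fit$fixed_estimates),
    estimate = unname(fit$fixed_estimates),
    boot_mean = colMeans(fx_mat),
    se = apply(fx_mat, 2, stats::sd),
    lo = apply(fx_mat, 2, qs, 0.025),
    hi = apply(fx_mat, 2, qs, 0.975),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(n_boot = n_boot, n_dropped = n_dropped, seed = seed,
                 refit_variance = refit_variance, summary = summ,
                 fixed = fixed),
            class = "bootstrap_summary")
}

# Refit with variance components frozen at the original estimates: only the
# fixed effects are re-optimised on the bootstrap sample.
.refit_fixed_only <- function(records, clones, fit) {
  spec <- fit$spec
  prep <- .prep_growth_data(records, clones)
  prep$Llo <- min(prep$L); prep$Lhi <- max(prep$L)
  nf <- if (spec$family == "A") 3 else 4
  par0 <- fit$par
  obj <- function(pf) {
    cache <- new.env(parent = emptyenv())
    .laplace_nll(c(pf, par0[-seq_len(nf)]), spec, prep, cache)
  }
  bounds <- .par_bounds(spec)
  opt <- stats::nlminb(par0[seq_len(nf)], obj,
                       lower = bounds$lower[seq_len(nf)],
                       upper = bounds$upper[seq_len(nf)])
  opt$par <- c(opt$par, par0[-seq_len(nf)])
  opt$converged <- opt$convergence == 0 ||
    grepl("relative convergence|X-convergence|singular convergence",
          opt$message %||% "")
  .build_fit(opt, spec, prep)
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf(
    "Residual bootstrap: %d replicates (%d dropped), seed %d, %s\n\n",
    x$n_boot, x$n_dropped, x$seed,
    if (x$refit_variance) "full refit" else "fixed variance components"))
  s <- x$summary
  num <- vapply(s, is.numeric, logical(1))
  s[num] <- lapply(s[num], round, 3)
  print(s, row.names = FALSE)
  invisible(x)
}
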