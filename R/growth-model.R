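#' Juvenile somatic growth rate from dry masses
#'
#' Computes the mass-specific juvenile growth rate
#' g = (ln Wt - ln W0) / t from initial and final individual dry mass over
#' an experiment of duration t.  Negative rates (mass loss) are allowed.
#'
#' @param W0 initial dry mass (ug), > 0.
#' @param Wt final dry mass (ug), > 0.
#' @param t duration (days), > 0.
#' @return Growth rate in day^-1.  Vectorised over all arguments.
#' @examples
#' juvenile_growth_rate(10, 10 * exp(1.2), 6)  # 0.2 day^-1
#' @export
juvenile_growth_rate <- function(W0, Wt, t) {
  if (any(!is.finite(W0)) || any(W0 <= 0))
    stop("initial mass W0 must be positive", call. = FALSE)
  if (any(!is.finite(Wt)) || any(Wt <= 0))
    stop("final mass Wt must be positive", call. = FALSE)
  if (any(!is.finite(t)) || any(t <= 0))
    stop("duration t must be positive", call. = FALSE)
  (log(Wt) - log(W0)) / t
}

#' Parameter set of the Monod-type growth response
#'
#' @param g0 baseline growth rate without dietary EPA (day^-1).
#' @param ginf asymptotic growth rate at saturating EPA (day^-1); must not
#'   fall below `g0` (the response saturates upward).
#' @param KS half-saturation constant (ug EPA mg C^-1), > 0.
#' @return An object of class `monod_params`.
#' @export
monod_params <- function(g0, ginf, KS) {
  stopifnot(is.numeric(g0), is.numeric(ginf), is.numeric(KS))
  if (!is.finite(KS) || KS <= 0) stop("KS must be positive", call. = FALSE)
  if (ginf < g0) stop("ginf must be >= g0", call. = FALSE)
  structure(list(g0 = g0, ginf = ginf, KS = KS), class = "monod_params")
}

#' @export
print.monod_params <- function(x, ...) {
  cat(sprintf("Monod growth parameters: g0 = %.4g, ginf = %.4g, KS = %.4g\n",
              x$g0, x$ginf, x$KS))
  invisible(x)
}

#' Monod-type saturation growth curve with baseline shift
#'
#' Expected juvenile growth rate at dietary EPA concentration S:
#' g(S) = g0 + (ginf - g0) * S / (S + KS).  g(0) = g0, g(KS) is the exact
#' midpoint of g0 and ginf, and g(S) increases towards ginf as S grows.
#'
#' @param S dietary EPA concentration (ug EPA mg C^-1), >= 0; vectorised.
#' @param p a [monod_params()] object, or a list with elements
#'   `g0`, `ginf`, `KS`.
#' @return Growth rate(s) in day^-1.
#' @examples
#' p <- monod_params(0.1, 0.5, 2)
#' monod_growth(c(0, 2, 6), p)  # 0.1, 0.3, 0.4
#' @export
monod_growth <- function(S, p) {
  if (any(!is.finite(S)) || any(S < 0))
    stop("EPA concentration S must be non-negative", call. = FALSE)
  p$g0 + (p$ginf - p$g0) * S / (S + p$KS)
}

#' Dietary EPA concentration reaching a given fraction of growth saturation
#'
#' Solves g(S) - g0 = p_frac * (ginf - g0) for S under the Monod-type
#' response, i.e. S = KS * p_frac / (1 - p_frac).  At `p_frac = 0.5` this is
#' the half-saturation constant itself; at `p_frac = 0.75` it equals 3 * KS,
#' the 75% saturation threshold used to compare EPA demands across clones.
#'
#' @param KS half-saturation constant (ug EPA mg C^-1), > 0; vectorised.
#' @param p_frac saturation fraction, strictly between 0 and 1 (the
#'   threshold diverges as `p_frac` approaches 1).
#' @return EPA concentration (ug EPA mg C^-1).
#' @examples
#' saturation_threshold(0.60, 0.75)  # 1.80
#' @export
saturation_threshold <- function(KS, p_frac) {
  if (any(!is.finite(KS)) || any(KS <= 0))
    stop("KS must be positive", call. = FALSE)
  if (length(p_frac) != 1 || !is.finite(p_frac) || p_frac <= 0 || p_frac >= 1)
    stop("p_frac must lie strictly in (0, 1)", call. = FALSE)
  KS * p_frac / (1 - p_frac)
}

#' Half-saturation constant from the linear body-size law
#'
#' Evaluates K_S = K0 + K_L * L, the size-dependent half-saturation
#' constant of the B-type models.
#'
#' @param law list with elements `K0` (intercept, ug EPA mg C^-1) and `KL`
#'   (slope, ug EPA mg C^-1 mm^-1), e.g. from [size_law_from_ks()].
#' @param L body size at first reproduction (mm); vectorised.
#' @return K_S in ug EPA mg C^-1.  Errors if any value is non-positive,
#'   since a non-positive half-saturation constant is meaningless.
#' @export
ks_from_size <- function(law, L) {
  ks <- law$K0 + law$KL * L
  if (any(!is.finite(ks)) || any(ks <= 0))
    stop("size law yields non-positive KS over the requested body sizes",
         call. = FALSE)
  ks
}

#' Arcsine-square-root transform scaled to the unit interval
#'
#' Variance-stabilising transform c' = 2 * asin(sqrt(c)) / pi for
#' proportion-scaled clutch data.  Fixed points at 0, 1/2 and 1; strictly
#' increasing on [0, 1].
#'
#' @param c proportions in [0, 1]; vectorised.
#' @return Transformed values in [0, 1].
#' @seealso [arcsin_sqrt_inverse()]
#' @export
arcsin_sqrt_transform <- function(c) {
  if (any(!is.finite(c)) || any(c < 0) || any(c > 1))
    stop("arcsin-sqrt transform requires values in [0, 1]", call. = FALSE)
  2 * asin(sqrt(c)) / pi
}

#' Inverse of the scaled arcsine-square-root transform
#'
#' @param cprime transformed values in [0, 1].
#' @return Proportions in [0, 1] with
#'   `arcsin_sqrt_inverse(arcsin_sqrt_transform(c)) == c`.
#' @export
arcsin_sqrt_inverse <- function(cprime) {
  if (any(!is.finite(cprime)) || any(cprime < 0) || any(cprime > 1))
    stop("inverse transform requires values in [0, 1]", call. = FALSE)
  sin(cprime * pi / 2)^2
}
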