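#' Gaussian liability-threshold model
#'
#' Disease occurs when a standard-normal latent liability, the sum of a
#' genetic component (the polygenic score, variance `r2`) and a residual
#' (variance `1 - r2`), exceeds the threshold set by the population
#' prevalence: `T = qnorm(1 - prevalence)`. This is the field-standard
#' generative model linking "top percentile of a PRS" to a concrete
#' disease risk, and it produces the familiar accelerating
#' risk-by-percentile curve.
#'
#' @param prevalence Population risk K, in (0, 1).
#' @param r2 Variance in liability explained by the score, in \[0, 1).
#'   `r2 = 1` would make risk a step function of the percentile and is
#'   rejected.
#' @return An object of class `liability_model` with elements
#'   `prevalence`, `r2`, `threshold`.
#' @examples
#' liability_model(0.02, 0.1)
#' @export
liability_model <- function(prevalence, r2) {
  check_fraction(prevalence, "prevalence")
  if (!is.numeric(r2) || length(r2) != 1L || !is.finite(r2) || r2 < 0)
    stop_domain("`r2` must be a single number in [0, 1)")
  if (r2 >= 1)
    stop_degenerate("r2 = 1 makes risk a deterministic step in the percentile")
  structure(
    list(prevalence = prevalence, r2 = r2,
         threshold = stats::qnorm(1 - prevalence)),
    class = "liability_model"
  )
}

#' Conditional disease risk at a score percentile
#'
#' For an individual exactly at percentile `q` of the genetic score, the
#' genetic liability is `g = sqrt(r2) qnorm(q)` and the conditional risk is
#' the upper-tail normal probability of the residual making up the rest:
#' `pnorm((T - g) / sqrt(1 - r2), lower.tail = FALSE)`.
#'
#' @param model A [liability_model()].
#' @param q Percentile(s) of the score, each strictly in (0, 1);
#'   vectorised.
#' @return Conditional risk fraction(s) in (0, 1); identically the
#'   prevalence when `r2 = 0`.
#' @examples
#' m <- liability_model(0.02, 0.1)
#' risk_at_percentile(m, c(0.5, 0.95, 0.99))
#' @export
risk_at_percentile <- function(model, q) {
  if (!inherits(model, "liability_model"))
    stop_domain("`model` must be a liability_model")
  if (!is.numeric(q) || any(!is.finite(q)) || any(q <= 0) || any(q >= 1))
    stop_domain("`q` must lie strictly in (0, 1)")
  g <- sqrt(model$r2) * stats::qnorm(q)
  stats::pnorm((model$threshold - g) / sqrt(1 - model$r2), lower.tail = FALSE)
}

# Integral of risk over score percentiles (u_lo, u_hi), i.e. the fraction
# of the whole population that both lies in that percentile band and
# develops disease. Computed after the substitution u = pnorm(z) so the
# integrand risk(z) * dnorm(z) is smooth; composite fixed-order
# Gauss-Legendre on the z scale, tail truncated at |z| = 8 (the omitted
# mass is below 1e-15).
.risk_mass <- function(model, u_lo, u_hi, n_bins = 24L, order = 16L) {
  z_lo <- if (u_lo <= 0) -8 else max(stats::qnorm(u_lo), -8)
  z_hi <- if (u_hi >= 1) 8 else min(stats::qnorm(u_hi), 8)
  if (z_hi <= z_lo) return(0)
  edges <- seq(z_lo, z_hi, length.out = n_bins + 1L)
  gl <- pracma::gaussLegendre(order, 0, 1)
  total <- 0
  a <- sqrt(model$r2)
  b <- sqrt(1 - model$r2)
  for (i in seq_len(n_bins)) {
    lo <- edges[i]; hi <- edges[i + 1L]
    z <- lo + (hi - lo) * gl$x
    f <- stats::pnorm((model$threshold - a * z) / b, lower.tail = FALSE) *
      stats::dnorm(z)
    total <- total + (hi - lo) * sum(gl$w * f)
  }
  total
}

#' Classification summary for targeting everyone above a percentile
#'
#' Treats "score above percentile `q`" as the positive call
#' (target fraction `t = 1 - q`), integrates the conditional risk over the
#' targeted band to obtain the true-positive mass, and summarises the
#' resulting population 2x2 table.
#'
#' @param model A [liability_model()].
#' @param q Percentile cutoff, strictly in (0, 1).
#' @return A `classification_summary` (see [summarize_confusion()]).
#' @examples
#' m <- liability_model(0.02, 0.2)
#' metrics_above_percentile(m, 0.95)$ppv
#' @export
metrics_above_percentile <- function(model, q) {
  if (!inherits(model, "liability_model"))
    stop_domain("`model` must be a liability_model")
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q <= 0 || q >= 1)
    stop_domain("`q` must lie strictly in (0, 1)")
  p <- model$prevalence
  t <- 1 - q
  tp <- .risk_mass(model, q, 1)
  tp <- min(tp, p, t)
  cf <- structure(
    list(tp = tp, fp = t - tp, fn = p - tp, tn = 1 - t - (p - tp),
         prevalence = p, target_fraction = t),
    class = "confusion_fractions"
  )
  summarize_confusion(cf)
}

#' Risk-by-percentile curve
#'
#' Evaluates the liability model on a percentile grid: per-bin average
#' risk, the fold increase of each bin's risk over the mean risk of all
#' lower percentiles, and the fraction of all cases found above each bin's
#' lower edge (the sensitivity of targeting upwards from there).
#'
#' @param model A [liability_model()].
#' @param bins Number of equal-width percentile bins (default 100).
#' @return A data.frame with one row per bin: `percentile` (upper edge),
#'   `risk` (average conditional risk in the bin), `fold_vs_below` (bin
#'   risk over mean risk of all lower bins; `NA` for the first bin),
#'   `sensitivity_above` and `ppv_above` (sensitivity and precision of
#'   calling positive everyone at or above the bin's lower edge).
#' @examples
#' head(risk_curve(liability_model(0.02, 0.1), bins = 20))
#' @export
risk_curve <- function(model, bins = 100L) {
  if (!inherits(model, "liability_model"))
    stop_domain("`model` must be a liability_model")
  bins <- as.integer(bins)
  if (is.na(bins) || bins < 2L)
    stop_domain("`bins` must be an integer >= 2")
  edges <- seq(0, 1, length.out = bins + 1L)
  width <- 1 / bins
  mass <- vapply(
    seq_len(bins),
    function(i) .risk_mass(model, edges[i], edges[i + 1L], n_bins = 4L),
    numeric(1)
  )
  risk <- mass / width
  cum_below <- c(0, cumsum(mass))[seq_len(bins)]       # case mass below bin
  mean_below <- ifelse(edges[seq_len(bins)] > 0,
                       cum_below / edges[seq_len(bins)], NA_real_)
  tail_mass <- rev(cumsum(rev(mass)))                   # case mass at/above lower edge
  tail_frac <- 1 - edges[seq_len(bins)]
  K <- sum(mass)
  data.frame(
    percentile = edges[-1L],
    risk = risk,
    fold_vs_below = risk / mean_below,
    sensitivity_above = tail_mass / K,
    ppv_above = tail_mass / tail_frac
  )
}

#' Calibrate score variance explained to a target relative risk
#'
#' Finds the `r2` at which targeting everyone above percentile `q` yields
#' the requested remainder-referenced relative risk, bridging percentile
#' targeting to scenarios quoted by RR. Monotone in `r2`, solved by
#' root-finding on the forward model.
#'
#' @param prevalence Population risk K, in (0, 1).
#' @param target_rr Desired relative risk, >= 1 and below the supremum
#'   reached as `r2` approaches 1.
#' @param q Percentile cutoff, strictly in (0, 1).
#' @param tol Convergence tolerance on RR (default 1e-8).
#' @return The calibrated `r2` in \[0, 1).
#' @examples
#' r2 <- calibrate_r2_to_rr(0.02, 4.7, 0.95)
#' metrics_above_percentile(liability_model(0.02, r2), 0.95)$relative_risk
#' @export
calibrate_r2_to_rr <- function(prevalence, target_rr, q, tol = 1e-8) {
  check_fraction(prevalence, "prevalence")
  check_fraction(q, "q")
  if (!is.numeric(target_rr) || length(target_rr) != 1L ||
      !is.finite(target_rr) || target_rr < 1)
    stop_domain("`target_rr` must be a single number >= 1")
  if (abs(target_rr - 1) < 1e-12) return(0)
  rr_at <- function(r2)
    metrics_above_percentile(liability_model(prevalence, r2), q)$relative_risk
  upper <- 1 - 1e-9
  if (rr_at(upper) < target_rr)
    stop_infeasible(sprintf(
      "relative risk %.4g is not achievable at prevalence %.4g and percentile %.4g (supremum %.4g)",
      target_rr, prevalence, q, rr_at(upper)
    ))
  stats::uniroot(function(r2) rr_at(r2) - target_rr,
                 lower = 0, upper = upper, tol = tol)$root
}
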