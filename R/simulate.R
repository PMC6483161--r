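#' Simulate an individual-level cohort under the liability model
#'
#' Draws a synthetic cohort that embodies the same assumptions as the
#' closed forms, so that simple counting can validate them: per-individual
#' genetic liability `g ~ N(0, r2)` and residual `e ~ N(0, 1 - r2)`,
#' disease when `g + e` exceeds the prevalence threshold, target
#' membership for the top `target_fraction` ranked by `g` (the score, not
#' the outcome, defines who is targeted), and a single counterfactual
#' response draw per individual at the group's effectiveness
#' (potential-outcome style, so prevented counts are consistent between a
#' treat-everyone and a treat-target policy).
#'
#' @param model A [liability_model()].
#' @param target_fraction Fraction of the cohort targeted, in (0, 1).
#' @param effectiveness An [effectiveness_model()].
#' @param n Number of individuals (>= 1).
#' @param seed Integer seed; the cohort is reproducible given the seed.
#' @return An object of class `synthetic_cohort`: a list with vectors
#'   `prs_liability`, `disease`, `in_target`, `would_respond` of length
#'   `n`, plus the generating `model`, `target_fraction`, `effectiveness`
#'   and `seed`.
#' @examples
#' m <- liability_model(0.02, 0.2)
#' co <- simulate_cohort(m, 0.05, effectiveness_model(0.9), n = 1e4, seed = 1)
#' mean(co$disease)
#' @export
simulate_cohort <- function(model, target_fraction, effectiveness, n, seed) {
  if (!inherits(model, "liability_model"))
    stop_domain("`model` must be a liability_model")
  check_fraction(target_fraction, "target_fraction")
  if (!inherits(effectiveness, "effectiveness_model"))
    stop_domain("`effectiveness` must be an effectiveness_model")
  n <- as.integer(n)
  if (is.na(n) || n < 1L)
    stop_domain("`n` must be a positive integer")
  seed <- as.integer(seed)
  if (is.na(seed)) stop_domain("`seed` must be an integer")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  g <- stats::rnorm(n, sd = sqrt(model$r2))
  e <- stats::rnorm(n, sd = sqrt(1 - model$r2))
  disease <- (g + e) > model$threshold
  n_target <- round(target_fraction * n)
  in_target <- logical(n)
  if (n_target > 0L)
    in_target[order(g, decreasing = TRUE)[seq_len(n_target)]] <- TRUE
  rate <- ifelse(in_target, effectiveness$effect_target,
                 effectiveness$effect_remainder)
  would_respond <- stats::runif(n) < rate

  structure(
    list(
      n = n,
      prs_liability = g,
      disease = disease,
      in_target = in_target,
      would_respond = would_respond,
      model = model,
      target_fraction = target_fraction,
      effectiveness = effectiveness,
      seed = seed
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> n = %d, prevalence %.3f (model %.3f), target %.3f, seed %d\n",
    x$n, mean(x$disease), x$model$prevalence, x$target_fraction, x$seed
  ))
  invisible(x)
}

#' Empirical metrics of a simulated cohort, by counting
#'
#' The Monte Carlo oracle: classification metrics, prevention fractions
#' and NNTs computed by direct counting over the cohort, with binomial
#' standard errors, for comparison with the closed forms at matched
#' parameters. "Prevented" counts come from the per-individual
#' counterfactual response draws: treating everyone prevents every
#' responding case; treating only the target prevents responding cases
#' inside it.
#'
#' @param cohort A [simulate_cohort()] result.
#' @return A list with components `summary` (a `classification_summary`),
#'   `intervention` (percent_preventable, percent_all_prevented, nnt_all,
#'   nnt_targeted from counts), `se` (binomial standard errors for ppv,
#'   npv, sensitivity, specificity, percent_preventable,
#'   percent_all_prevented) and `counts` (the raw cell counts).
#' @export
empirical_metrics <- function(cohort) {
  if (!inherits(cohort, "synthetic_cohort"))
    stop_domain("`cohort` must be a synthetic_cohort")
  d <- cohort$disease
  tgt <- cohort$in_target
  resp <- cohort$would_respond
  n <- cohort$n
  if (!any(d) || all(d))
    stop_degenerate("cohort needs at least one case and one non-case")

  tp <- sum(d & tgt); fp <- sum(!d & tgt)
  fn <- sum(d & !tgt); tn <- sum(!d & !tgt)
  if (tp + fp == 0L || tn + fn == 0L)
    stop_degenerate("empty target or remainder group")

  cf <- structure(
    list(tp = tp / n, fp = fp / n, fn = fn / n, tn = tn / n,
         prevalence = (tp + fn) / n, target_fraction = (tp + fp) / n),
    class = "confusion_fractions"
  )
  summ <- summarize_confusion(cf)

  prevented_target <- sum(d & tgt & resp)
  preventable_all <- sum(d & resp)
  cases <- tp + fn
  interv <- list(
    percent_preventable = if (preventable_all > 0) prevented_target / preventable_all else NA_real_,
    percent_all_prevented = prevented_target / cases,
    nnt_all = if (preventable_all > 0) n / preventable_all else Inf,
    nnt_targeted = if (prevented_target > 0) (tp + fp) / prevented_target else Inf
  )

  binom_se <- function(phat, m) if (m > 0) sqrt(phat * (1 - phat) / m) else NA_real_
  se <- list(
    ppv = binom_se(summ$ppv, tp + fp),
    npv = binom_se(summ$npv, tn + fn),
    sensitivity = binom_se(summ$sensitivity, cases),
    specificity = binom_se(summ$specificity, fp + tn),
    percent_preventable = binom_se(interv$percent_preventable, preventable_all),
    percent_all_prevented = binom_se(interv$percent_all_prevented, cases)
  )

  list(
    summary = summ,
    intervention = interv,
    se = se,
    counts = list(tp = tp, fp = fp, fn = fn, tn = tn,
                  prevented_target = prevented_target,
                  preventable_all = preventable_all, n = n)
  )
}

#' Export a cohort as a data.frame (one row per individual)
#'
#' @param x A `synthetic_cohort`.
#' @param ... Unused.
#' @return A data.frame with columns `prs_liability`, `disease`,
#'   `in_target`, `would_respond`.
#' @export
as.data.frame.synthetic_cohort <- function(x, ...) {
  data.frame(
    prs_liability = x$prs_liability,
    disease = as.integer(x$disease),
    in_target = as.integer(x$in_target),
    would_respond = as.integer(x$would_respond)
  )
}
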