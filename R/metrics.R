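#' riskstrat: clinical utility of risk-stratified intervention
#'
#' Closed-form confusion-matrix algebra for risk-score-targeted intervention,
#' prevention fractions and the number needed to treat (NNT), a Gaussian
#' liability-threshold risk-percentile model, and a Monte Carlo cohort
#' simulator that cross-validates every closed form by counting.
#'
#' All quantities are handled internally as plain fractions in \[0, 1\];
#' percentages appear only at input/output boundaries (see
#' [round_percent()]).
#'
#' @keywords internal
"_PACKAGE"

# Error helpers: every user-facing failure carries a condition class so
# callers (and the CLI) can distinguish bad parameters from infeasible
# scenario algebra.
stop_domain <- function(msg) {
  stop(errorCondition(msg, class = c("riskstrat_domain_error", "riskstrat_error")))
}

stop_infeasible <- function(msg) {
  stop(errorCondition(msg, class = c("riskstrat_infeasible_error", "riskstrat_error")))
}

stop_degenerate <- function(msg) {
  stop(errorCondition(msg, class = c("riskstrat_degenerate_error", "riskstrat_error")))
}

check_fraction <- function(x, name, open_left = TRUE, open_right = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_domain(sprintf("`%s` must be a single finite number", name))
  lo_ok <- if (open_left) x > 0 else x >= 0
  hi_ok <- if (open_right) x < 1 else x <= 1
  if (!lo_ok || !hi_ok)
    stop_domain(sprintf(
      "`%s` = %g is outside %s0, 1%s", name, x,
      if (open_left) "(" else "[", if (open_right) ")" else "]"
    ))
  invisible(x)
}

#' Define a cohort scenario
#'
#' A scenario is the atomic input unit of the calculator: the population
#' prevalence of the condition, the fraction of the population called
#' positive (the target group, e.g. the top tail of a polygenic score), and
#' exactly one discrimination parameter describing how well the score
#' separates cases from non-cases. Any one of the three discrimination
#' parametrisations determines the other two once prevalence and target
#' fraction are fixed.
#'
#' @param prevalence Fraction of the population affected, strictly in (0, 1).
#' @param target_fraction Fraction of the population called positive,
#'   strictly in (0, 1).
#' @param sensitivity Fraction of all cases falling inside the target group,
#'   in (0, 1\].
#' @param relative_risk Prevalence in the target group divided by prevalence
#'   in the remainder (the untargeted 1 - t of the population); must be > 0.
#'   This is the "relative risk" (sometimes loosely "odds ratio") used when
#'   quoting the risk concentration of a score tail against everyone else.
#' @param ppv Positive predictive value (precision) of target membership, in
#'   (0, 1\].
#'
#' Supply exactly one of `sensitivity`, `relative_risk`, `ppv`.
#'
#' @return An object of class `cohort_scenario`: a list with elements
#'   `prevalence`, `target_fraction`, `sensitivity` (the resolved value),
#'   `discrimination` (the name of the parameter that was supplied) and
#'   `discrimination_value`.
#' @examples
#' cohort_scenario(0.02, 0.05, relative_risk = 4.7)
#' cohort_scenario(0.08, 0.05, ppv = 0.5)
#' @export
cohort_scenario <- function(prevalence, target_fraction,
                            sensitivity = NULL, relative_risk = NULL,
                            ppv = NULL) {
  check_fraction(prevalence, "prevalence")
  check_fraction(target_fraction, "target_fraction")
  given <- c(
    sensitivity = !is.null(sensitivity),
    relative_risk = !is.null(relative_risk),
    ppv = !is.null(ppv)
  )
  if (sum(given) != 1L)
    stop_domain("supply exactly one of `sensitivity`, `relative_risk`, `ppv`")
  tag <- names(given)[given]
  s <- switch(tag,
    sensitivity = {
      check_fraction(sensitivity, "sensitivity", open_right = FALSE)
      sensitivity
    },
    relative_risk = sensitivity_from_relative_risk(relative_risk, target_fraction),
    ppv = sensitivity_from_ppv(ppv, prevalence, target_fraction)
  )
  # Feasibility: PPV <= 1 and NPV >= 0 in the implied 2x2 table.
  if (s * prevalence > target_fraction + 1e-12)
    stop_infeasible(sprintf(
      "infeasible scenario: sensitivity %.4f at prevalence %.4f implies PPV > 1 for target fraction %.4f",
      s, prevalence, target_fraction
    ))
  if ((1 - s) * prevalence > (1 - target_fraction) + 1e-12)
    stop_infeasible(sprintf(
      "infeasible scenario: missed cases (%.4f) exceed the remainder fraction %.4f",
      (1 - s) * prevalence, 1 - target_fraction
    ))
  structure(
    list(
      prevalence = prevalence,
      target_fraction = target_fraction,
      sensitivity = s,
      discrimination = tag,
      discrimination_value = switch(tag,
        sensitivity = sensitivity,
        relative_risk = relative_risk,
        ppv = ppv
      )
    ),
    class = "cohort_scenario"
  )
}

#' @export
print.cohort_scenario <- function(x, ...) {
  cat(sprintf(
    "<cohort_scenario> prevalence %.4g, target %.4g, %s = %.4g (sensitivity %.4g)\n",
    x$prevalence, x$target_fraction, x$discrimination,
    x$discrimination_value, x$sensitivity
  ))
  invisible(x)
}

#' Sensitivity implied by a remainder-referenced relative risk
#'
#' Solves the defining ratio RR = \[s p / t\] / \[(1 - s) p / (1 - t)\] for
#' the sensitivity s: the prevalence cancels, giving
#' \deqn{s = \frac{RR\,t}{1 - t + RR\,t}.}
#' A score tail quoted as "top t with relative risk RR" therefore captures
#' this fraction of all eventual cases, whatever the disease prevalence.
#'
#' @param relative_risk Target-group prevalence over remainder-group
#'   prevalence; > 0.
#' @param target_fraction Fraction of the population called positive, in
#'   (0, 1).
#' @return Sensitivity as a fraction in (0, 1).
#' @examples
#' sensitivity_from_relative_risk(9, 0.10)   # 0.5
#' sensitivity_from_relative_risk(1, 0.25)   # no discrimination: equals t
#' @export
sensitivity_from_relative_risk <- function(relative_risk, target_fraction) {
  if (!is.numeric(relative_risk) || length(relative_risk) != 1L ||
      !is.finite(relative_risk) || relative_risk <= 0)
    stop_domain("`relative_risk` must be a single positive number")
  check_fraction(target_fraction, "target_fraction")
  rt <- relative_risk * target_fraction
  rt / (1 - target_fraction + rt)
}

#' Sensitivity implied by a precision target
#'
#' Inverts PPV = s p / t. Used for scenarios quoted by precision ("a test
#' with a precision of at least 50% targeting 5% of the population").
#'
#' @param ppv Positive predictive value, in (0, 1\].
#' @param prevalence Population prevalence, in (0, 1).
#' @param target_fraction Fraction called positive, in (0, 1).
#' @return Sensitivity s = ppv t / p; an error if the combination would
#'   require s > 1 (more captured cases than exist).
#' @export
sensitivity_from_ppv <- function(ppv, prevalence, target_fraction) {
  check_fraction(ppv, "ppv", open_right = FALSE)
  check_fraction(prevalence, "prevalence")
  check_fraction(target_fraction, "target_fraction")
  s <- ppv * target_fraction / prevalence
  if (s > 1 + 1e-12)
    stop_infeasible(sprintf(
      "infeasible scenario: PPV %.4g at target %.4g needs %.4g of cases, but sensitivity cannot exceed 1",
      ppv, target_fraction, s
    ))
  min(s, 1)
}

#' Population 2x2 table for a scenario
#'
#' Builds the confusion matrix implied by a scenario, with each cell a
#' fraction of the whole population: `tp = s p`, `fn = (1 - s) p`,
#' `fp = t - tp`, `tn = 1 - t - fn`.
#'
#' @param scenario A [cohort_scenario()].
#' @return An object of class `confusion_fractions` with elements `tp`,
#'   `fp`, `fn`, `tn` summing to 1, plus the originating `prevalence` and
#'   `target_fraction`.
#' @export
confusion_from_scenario <- function(scenario) {
  if (!inherits(scenario, "cohort_scenario"))
    stop_domain("`scenario` must be a cohort_scenario")
  p <- scenario$prevalence
  t <- scenario$target_fraction
  s <- scenario$sensitivity
  tp <- s * p
  fn <- (1 - s) * p
  fp <- t - tp
  tn <- 1 - t - fn
  if (fp < -1e-12 || tn < -1e-12)
    stop_infeasible("infeasible scenario: negative cell in the implied 2x2 table")
  structure(
    list(tp = tp, fp = max(fp, 0), fn = fn, tn = max(tn, 0),
         prevalence = p, target_fraction = t),
    class = "confusion_fractions"
  )
}

#' Classification summary from population confusion fractions
#'
#' @param confusion A `confusion_fractions` object (see
#'   [confusion_from_scenario()]), or anything list-like with numeric
#'   elements `tp`, `fp`, `fn`, `tn` that are non-negative and sum to 1.
#' @return An object of class `classification_summary` with fractions
#'   `ppv`, `npv`, `sensitivity`, `specificity`, `accuracy` and the
#'   dimensionless `relative_risk` = ppv / (prevalence among the
#'   remainder) = ppv / (1 - npv).
#' @export
summarize_confusion <- function(confusion) {
  cf <- confusion
  cells <- c(cf$tp, cf$fp, cf$fn, cf$tn)
  if (length(cells) != 4L || !all(is.finite(cells)) || any(cells < -1e-12))
    stop_domain("confusion fractions must be four finite non-negative numbers")
  if (abs(sum(cells) - 1) > 1e-9)
    stop_domain("confusion fractions must sum to 1")
  denom <- list(
    ppv = cf$tp + cf$fp,
    npv = cf$tn + cf$fn,
    sensitivity = cf$tp + cf$fn,
    specificity = cf$tn + cf$fp
  )
  bad <- names(denom)[vapply(denom, function(d) d <= 0, logical(1))]
  if (length(bad))
    stop_degenerate(paste0(
      "degenerate scenario: zero denominator for ", paste(bad, collapse = ", ")
    ))
  remainder_prev <- cf$fn / (cf$fn + cf$tn)
  structure(
    list(
      ppv = cf$tp / denom$ppv,
      npv = cf$tn / denom$npv,
      sensitivity = cf$tp / denom$sensitivity,
      specificity = cf$tn / denom$specificity,
      accuracy = cf$tp + cf$tn,
      relative_risk = if (remainder_prev > 0) (cf$tp / denom$ppv) / remainder_prev else Inf
    ),
    class = "classification_summary"
  )
}

#' @export
print.classification_summary <- function(x, ...) {
  cat("<classification_summary>\n")
  for (nm in c("ppv", "npv", "sensitivity", "specificity", "accuracy"))
    cat(sprintf("  %-12s %6.2f%%\n", nm, 100 * x[[nm]]))
  cat(sprintf("  %-12s %6.2f\n", "rel. risk", x$relative_risk))
  invisible(x)
}

#' One-call classification summary for a scenario
#'
#' Convenience wrapper: [confusion_from_scenario()] followed by
#' [summarize_confusion()].
#'
#' @inheritParams confusion_from_scenario
#' @return A `classification_summary`.
#' @examples
#' scenario_metrics(cohort_scenario(0.02, 0.05, relative_risk = 4.7))$ppv
#' @export
scenario_metrics <- function(scenario) {
  summarize_confusion(confusion_from_scenario(scenario))
}

#' Round a fraction to an integer percentage
#'
#' Rounds half away from zero (so 0.5% prints as 1), matching how summary
#' tables in this field render integer percentages. Exact .5 ties are
#' detected with a 1e-9 absolute guard on the scaled value so that closed
#' forms whose binary representation lands infinitesimally below a tie
#' (e.g. 0.25 * 0.9 = 22.5%) still round up.
#'
#' @param x A non-negative fraction (vectorised).
#' @return Integer percent, `round(100 x)` with halves away from zero.
#' @examples
#' round_percent(0.9379)  # 94
#' round_percent(0.005)   # 1
#' @export
round_percent <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0))
    stop_domain("`x` must be non-negative and finite")
  round_half_away(100 * x)
}

# Nearest integer, halves away from zero, with a tiny tie guard for
# floating-point noise. Used for percents and for NNT rendering.
round_half_away <- function(x) {
  as.integer(floor(abs(x) + 0.5 + 1e-9) * sign(x))
}
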