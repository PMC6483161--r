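#' Treatment effectiveness model
#'
#' Effectiveness is the proportion of treated cases whose event is
#' prevented. It may differ between the target group and the remainder,
#' e.g. 75% in the high-risk tail and 25% elsewhere when responders are
#' concentrated among the genetically at-risk.
#'
#' @param effect_target Fraction of treated target-group cases prevented,
#'   in \[0, 1\].
#' @param effect_remainder Fraction of treated remainder-group cases
#'   prevented, in \[0, 1\]; defaults to `effect_target` (uniform model).
#' @return An object of class `effectiveness_model`.
#' @examples
#' effectiveness_model(0.9)          # uniform 90%
#' effectiveness_model(0.75, 0.25)   # differential response
#' @export
effectiveness_model <- function(effect_target, effect_remainder = effect_target) {
  check_fraction(effect_target, "effect_target", open_left = FALSE, open_right = FALSE)
  check_fraction(effect_remainder, "effect_remainder", open_left = FALSE, open_right = FALSE)
  structure(
    list(effect_target = effect_target, effect_remainder = effect_remainder),
    class = "effectiveness_model"
  )
}

#' Prevention fractions and NNT for a targeted intervention
#'
#' Combines a scenario's classification algebra with treatment
#' effectiveness to answer the policy questions: treating only the target
#' group, what fraction of all preventable events do we avert, what
#' fraction of all cases, and at what number needed to treat?
#'
#' With sensitivity s, prevalence p, PPV and effectiveness (e_t, e_r):
#' * cases prevented by target-only treatment: `s p e_t`
#' * cases prevented if everyone is treated: `p (s e_t + (1 - s) e_r)`
#' * `percent_preventable` is the ratio of the two;
#' * `percent_all_prevented = s e_t` (fraction of *all* cases);
#' * `nnt_all = 1 / (p (s e_t + (1 - s) e_r))` (whole population treated);
#' * `nnt_targeted = t / (s p e_t) = 1 / (ppv e_t)`.
#'
#' Under uniform effectiveness `percent_preventable` collapses to the
#' sensitivity and `nnt_all` to `1 / (p e)`.
#'
#' @param scenario A [cohort_scenario()].
#' @param effectiveness An [effectiveness_model()].
#' @return An object of class `intervention_outcome`: raw fractions
#'   `percent_preventable`, `percent_all_prevented`, raw `nnt_all`,
#'   `nnt_targeted`, and their integer display renderings
#'   `percent_preventable_pct`, `percent_all_prevented_pct`,
#'   `nnt_all_int`, `nnt_targeted_int`.
#' @examples
#' sc <- cohort_scenario(0.02, 0.05, relative_risk = 4.7)
#' intervention_outcomes(sc, effectiveness_model(0.9))
#' @export
intervention_outcomes <- function(scenario, effectiveness) {
  if (!inherits(scenario, "cohort_scenario"))
    stop_domain("`scenario` must be a cohort_scenario")
  if (!inherits(effectiveness, "effectiveness_model"))
    stop_domain("`effectiveness` must be an effectiveness_model")
  p <- scenario$prevalence
  t <- scenario$target_fraction
  s <- scenario$sensitivity
  e_t <- effectiveness$effect_target
  e_r <- effectiveness$effect_remainder
  prevented_target <- s * p * e_t
  preventable_all <- p * (s * e_t + (1 - s) * e_r)
  if (preventable_all <= 0)
    stop_degenerate("no preventable events: both effectiveness terms are zero")
  structure(
    list(
      percent_preventable = prevented_target / preventable_all,
      percent_all_prevented = s * e_t,
      nnt_all = 1 / preventable_all,
      nnt_targeted = if (prevented_target > 0) t / prevented_target else Inf,
      percent_preventable_pct = round_percent(prevented_target / preventable_all),
      percent_all_prevented_pct = round_percent(s * e_t),
      nnt_all_int = round_half_away(1 / preventable_all),
      nnt_targeted_int = if (prevented_target > 0) round_half_away(t / prevented_target) else NA_integer_
    ),
    class = "intervention_outcome"
  )
}

#' @export
print.intervention_outcome <- function(x, ...) {
  cat("<intervention_outcome>\n")
  cat(sprintf("  percent of preventable  %5.1f%%\n", 100 * x$percent_preventable))
  cat(sprintf("  percent of all prevented%5.1f%%\n", 100 * x$percent_all_prevented))
  cat(sprintf("  NNT all                 %7.2f\n", x$nnt_all))
  cat(sprintf("  NNT targeted            %7.2f\n", x$nnt_targeted))
  invisible(x)
}

#' Relative risk required to reach a precision goal
#'
#' Exact inversion of the forward map PPV(RR) = RR p / (1 - t + RR t):
#' \deqn{RR = \frac{ppv (1 - t)}{p - ppv\,t}.}
#' Answers "what score strength is needed so that targeting the top t of
#' the population reaches the stated precision?".
#'
#' @param ppv_goal Desired positive predictive value, in (0, 1\].
#' @param prevalence Population prevalence, in (0, 1).
#' @param target_fraction Fraction called positive, in (0, 1).
#' @return The remainder-referenced relative risk; forward evaluation at
#'   this RR reproduces `ppv_goal` to machine precision.
#' @examples
#' required_rr_for_precision(0.50, 0.08, 0.05)  # ~8.64
#' @export
required_rr_for_precision <- function(ppv_goal, prevalence, target_fraction) {
  check_fraction(ppv_goal, "ppv_goal", open_right = FALSE)
  check_fraction(prevalence, "prevalence")
  check_fraction(target_fraction, "target_fraction")
  if (ppv_goal * target_fraction > prevalence)
    stop_infeasible(sprintf(
      "infeasible goal: PPV %.4g at target %.4g would need more cases than the prevalence %.4g provides",
      ppv_goal, target_fraction, prevalence
    ))
  ppv_goal * (1 - target_fraction) / (prevalence - ppv_goal * target_fraction)
}

#' Cases prevented via a negative predictor (two-group mixture)
#'
#' Models a negative predictor that labels a `low_fraction` of the
#' population as having `low_risk_ratio` times the risk of the remaining
#' high-risk group, with the two group risks solved so the mixture equals
#' the overall prevalence. Resources are then focused on the high-risk
#' group, where intervention succeeds in a `success_rate` fraction of its
#' cases.
#'
#' @param prevalence Overall prevalence, in (0, 1).
#' @param low_fraction Fraction of the population labelled low risk, in
#'   (0, 1).
#' @param low_risk_ratio Low-group risk divided by high-group risk, in
#'   (0, 1\].
#' @param success_rate Fraction of high-group cases prevented by the
#'   intervention, in \[0, 1\].
#' @return Fraction of all cases prevented:
#'   `success_rate * high_risk * (1 - low_fraction) / prevalence`.
#' @examples
#' # low-risk two-thirds at half the risk, succeed in half the rest:
#' two_group_prevention(0.08, 2 / 3, 0.5, 0.5)  # 0.25
#' @export
two_group_prevention <- function(prevalence, low_fraction, low_risk_ratio,
                                 success_rate) {
  check_fraction(prevalence, "prevalence")
  check_fraction(low_fraction, "low_fraction")
  check_fraction(low_risk_ratio, "low_risk_ratio", open_right = FALSE)
  check_fraction(success_rate, "success_rate", open_left = FALSE, open_right = FALSE)
  # mixture: low_fraction * r_low + (1 - low_fraction) * r_high = prevalence
  r_high <- prevalence / (low_fraction * low_risk_ratio + (1 - low_fraction))
  r_low <- low_risk_ratio * r_high
  if (r_high > 1 || r_low > 1)
    stop_infeasible("infeasible mixture: implied group risk exceeds 1")
  high_case_share <- r_high * (1 - low_fraction) / prevalence
  success_rate * high_case_share
}
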