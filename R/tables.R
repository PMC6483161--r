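#' Build a scenario set
#'
#' A scenario set is an ordered collection of labelled columns, each a
#' [cohort_scenario()] paired with an [effectiveness_model()], evaluated
#' together into a summary table.
#'
#' @param name Label for the set.
#' @param columns A named list; each element is a list with components
#'   `scenario` (a `cohort_scenario`) and `effectiveness` (an
#'   `effectiveness_model`). Names are the column labels and must be
#'   unique.
#' @return An object of class `scenario_set`.
#' @export
scenario_set <- function(name, columns) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_domain("`name` must be a non-empty string")
  if (!is.list(columns) || length(columns) == 0L)
    stop_domain("`columns` must be a non-empty named list")
  labels <- names(columns)
  if (is.null(labels) || any(!nzchar(labels)) || anyDuplicated(labels))
    stop_domain("column labels must be present and unique")
  for (lab in labels) {
    col <- columns[[lab]]
    if (!inherits(col$scenario, "cohort_scenario") ||
        !inherits(col$effectiveness, "effectiveness_model"))
      stop_domain(sprintf(
        "column '%s' must contain a cohort_scenario and an effectiveness_model", lab
      ))
  }
  structure(list(name = name, columns = columns), class = "scenario_set")
}

# Ordered metric labels, matching the layout of published
# prevalence/RR/response/NNT summary tables.
.table_rows <- c(
  "Prevalence", "Relative Risk", "Target", "PPV/Precision", "NPV",
  "Accuracy", "Sensitivity", "Specificity", "Effectiveness",
  "Percent of Preventable", "Percent of All Prevented",
  "NNT All", "NNT Targeted"
)

#' Evaluate a scenario set into a summary table
#'
#' Runs the closed-form calculator on every column and assembles the
#' standard table: inputs (prevalence, relative risk, target,
#' effectiveness) and outputs (PPV, NPV, accuracy, sensitivity,
#' specificity, prevention fractions, NNTs), both as raw fractions and as
#' display-style integer percentages.
#'
#' @param set A [scenario_set()].
#' @return An object of class `scenario_table`: list with `name`,
#'   `raw` (data.frame, metric rows x columns, fractions and raw NNTs) and
#'   `rounded` (data.frame of display values: integer percents, integer
#'   NNTs, effectiveness as "90%" or "75/25%").
#' @examples
#' sc <- cohort_scenario(0.02, 0.05, relative_risk = 4.7)
#' st <- scenario_set("demo", list(col1 = list(
#'   scenario = sc, effectiveness = effectiveness_model(0.9))))
#' evaluate_set(st)$rounded
#' @export
evaluate_set <- function(set) {
  if (!inherits(set, "scenario_set"))
    stop_domain("`set` must be a scenario_set")
  labels <- names(set$columns)
  raw <- matrix(NA_real_, nrow = length(.table_rows), ncol = length(labels),
                dimnames = list(.table_rows, labels))
  disp <- matrix(NA_character_, nrow = length(.table_rows), ncol = length(labels),
                 dimnames = list(.table_rows, labels))
  for (lab in labels) {
    col <- set$columns[[lab]]
    sc <- col$scenario
    eff <- col$effectiveness
    summ <- tryCatch(
      scenario_metrics(sc),
      riskstrat_error = function(e) stop_infeasible(
        sprintf("column '%s': %s", lab, conditionMessage(e))
      )
    )
    out <- intervention_outcomes(sc, eff)
    raw[, lab] <- c(
      sc$prevalence, summ$relative_risk, sc$target_fraction,
      summ$ppv, summ$npv, summ$accuracy, summ$sensitivity, summ$specificity,
      eff$effect_target,
      out$percent_preventable, out$percent_all_prevented,
      out$nnt_all, out$nnt_targeted
    )
    eff_disp <- if (eff$effect_target == eff$effect_remainder) {
      sprintf("%s%%", format(100 * eff$effect_target))
    } else {
      sprintf("%s/%s%%", format(100 * eff$effect_target),
              format(100 * eff$effect_remainder))
    }
    disp[, lab] <- c(
      format(100 * sc$prevalence),
      format(round(summ$relative_risk, 1)),
      sprintf("%s%%", format(100 * sc$target_fraction)),
      as.character(round_percent(summ$ppv)),
      as.character(round_percent(summ$npv)),
      as.character(round_percent(summ$accuracy)),
      as.character(round_percent(summ$sensitivity)),
      as.character(round_percent(summ$specificity)),
      eff_disp,
      sprintf("%d%%", out$percent_preventable_pct),
      sprintf("%d%%", out$percent_all_prevented_pct),
      as.character(out$nnt_all_int),
      as.character(out$nnt_targeted_int)
    )
  }
  structure(
    list(
      name = set$name,
      raw = as.data.frame(raw),
      rounded = as.data.frame(disp)
    ),
    class = "scenario_table"
  )
}

#' @export
print.scenario_table <- function(x, ...) {
  cat(sprintf("<scenario_table> %s\n", x$name))
  print(x$rounded)
  invisible(x)
}

#' Write a scenario table as TSV
#'
#' Publication-style rendering: an `Attribute` column of metric labels followed
#' by one column per scenario; percent rows as integers.
#'
#' @param table A `scenario_table` from [evaluate_set()].
#' @param path Output file path ("" for stdout).
#' @return `path`, invisibly.
#' @export
write_scenario_tsv <- function(table, path = "") {
  if (!inherits(table, "scenario_table"))
    stop_domain("`table` must be a scenario_table")
  df <- cbind(Attribute = rownames(table$rounded), table$rounded)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.column_keys <- c("prevalence", "target", "rr", "sensitivity", "ppv",
                  "effect_target", "effect_remainder")

#' Parse a scenario-set configuration
#'
#' The configuration is a flat, human-writable key-value document. A
#' `name = <label>` line may appear before the first column. Each column
#' opens with a `[column] <label>` header followed by `key = value` lines:
#' `prevalence` and `target` (fractions), exactly one of `rr`,
#' `sensitivity`, `ppv`, and `effect_target` with optional
#' `effect_remainder` (defaults to `effect_target`). Blank lines and
#' `#` comments are ignored; unknown or duplicate keys are rejected with
#' the offending line number.
#'
#' @param config_text Character vector of configuration lines, or a single
#'   string with embedded newlines.
#' @return A validated [scenario_set()].
#' @examples
#' load_scenarios(c(
#'   "name = demo",
#'   "[column] only",
#'   "prevalence = 0.02", "target = 0.05",
#'   "rr = 4.7", "effect_target = 0.9"
#' ))
#' @export
load_scenarios <- function(config_text) {
  if (!is.character(config_text))
    stop_domain("`config_text` must be character")
  lines <- unlist(strsplit(config_text, "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)

  parse_error <- function(i, msg) stop_domain(sprintf("config line %d: %s", i, msg))

  set_name <- NULL
  columns <- list()
  current <- NULL
  current_label <- NULL

  finish_column <- function(fields, label) {
    for (k in c("prevalence", "target", "effect_target"))
      if (is.null(fields[[k]]))
        stop_domain(sprintf("column '%s': missing required key '%s'", label, k))
    disc <- intersect(c("rr", "sensitivity", "ppv"), names(fields))
    if (length(disc) != 1L)
      stop_domain(sprintf(
        "column '%s': exactly one of rr/sensitivity/ppv required, found %d",
        label, length(disc)
      ))
    sc <- tryCatch(
      switch(disc,
        rr = cohort_scenario(fields$prevalence, fields$target,
                             relative_risk = fields$rr),
        sensitivity = cohort_scenario(fields$prevalence, fields$target,
                                      sensitivity = fields$sensitivity),
        ppv = cohort_scenario(fields$prevalence, fields$target, ppv = fields$ppv)
      ),
      riskstrat_error = function(e) stop(errorCondition(
        sprintf("column '%s': %s", label, conditionMessage(e)), class = class(e)
      ))
    )
    eff <- effectiveness_model(
      fields$effect_target,
      if (is.null(fields$effect_remainder)) fields$effect_target
      else fields$effect_remainder
    )
    list(scenario = sc, effectiveness = eff)
  }

  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line)) next
    if (grepl("^\\[column\\]", line)) {
      if (!is.null(current)) {
        if (current_label %in% names(columns))
          parse_error(i, sprintf("duplicate column label '%s'", current_label))
        columns[[current_label]] <- finish_column(current, current_label)
      }
      current_label <- trimws(sub("^\\[column\\]", "", line))
      if (!nzchar(current_label)) parse_error(i, "column header needs a label")
      current <- list()
      next
    }
    kv <- regmatches(line, regexec("^([A-Za-z_]+)\\s*=\\s*(.+)$", line))[[1]]
    if (length(kv) != 3L)
      parse_error(i, sprintf("expected 'key = value', got '%s'", line))
    key <- kv[2]; val <- trimws(kv[3])
    if (is.null(current)) {
      if (key != "name")
        parse_error(i, sprintf("key '%s' before any [column] header", key))
      set_name <- val
      next
    }
    if (!key %in% .column_keys)
      parse_error(i, sprintf("unknown key '%s'", key))
    if (!is.null(current[[key]]))
      parse_error(i, sprintf("duplicate key '%s' in column '%s'", key, current_label))
    num <- suppressWarnings(as.numeric(val))
    if (is.na(num)) parse_error(i, sprintf("value for '%s' is not numeric: '%s'", key, val))
    current[[key]] <- num
  }
  if (!is.null(current)) {
    if (current_label %in% names(columns))
      stop_domain(sprintf("duplicate column label '%s'", current_label))
    columns[[current_label]] <- finish_column(current, current_label)
  }
  if (length(columns) == 0L)
    stop_domain("config defines no columns")
  scenario_set(if (is.null(set_name)) "scenarios" else set_name, columns)
}

#' Read a scenario-set configuration file
#'
#' @param path Path to a configuration file (see [load_scenarios()] for
#'   the format).
#' @return A [scenario_set()].
#' @export
read_scenarios <- function(path) {
  if (!file.exists(path)) stop_domain(sprintf("no such config file: %s", path))
  load_scenarios(readLines(path, warn = FALSE))
}

#' Shipped scenario presets
#'
#' Two preset sets mirror the modelled and approximate-observed summary
#' tables: `"table1"` (sixteen modelled columns spanning rare/common
#' prevalence, a range of relative risks and target fractions, and
#' uniform 90%/50% plus differential 75%/25% effectiveness) and
#' `"table2"` (eleven columns of approximate observed scenarios for
#' opioid use disorder, coronary events, and bone fracture).
#'
#' @param name `"table1"` or `"table2"`.
#' @return A [scenario_set()].
#' @examples
#' evaluate_set(preset_scenarios("table2"))
#' @export
preset_scenarios <- function(name = c("table1", "table2")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".cfg"), package = "riskstrat")
  if (!nzchar(path))
    stop_domain(sprintf("preset '%s' not found in installed package", name))
  read_scenarios(path)
}
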