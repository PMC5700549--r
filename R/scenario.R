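#' @title Scenario sensitivity analysis
#' @description Tables of the posterior probability of a target state (by
#'   default stress = Yes) across a Cartesian grid of evidence
#'   combinations, optionally under extra fixed evidence — the network
#'   analogue of the published demand/control/support/recognition
#'   sensitivity tables.
#' @name scenario
NULL

#' Define a scenario specification
#'
#' @param target target variable name (default `"stress"`).
#' @param target_state target state whose posterior is tabulated
#'   (default `"Yes"`).
#' @param grid named list: for each grid variable, the states to sweep, in
#'   row order. The first variable varies slowest (nested-table layout).
#'   An empty grid yields the single baseline row.
#' @param fixed named list of extra evidence applied to every row (e.g.
#'   a gender or age condition).
#' @return object of class `stressbn_scenario_spec`.
#' @export
scenario_spec <- function(target = "stress", target_state = "Yes",
                          grid = list(), fixed = list()) {
  vars <- names(grid)
  if (length(grid) && (is.null(vars) || any(vars == ""))) {
    stop("grid must be a named list", call. = FALSE)
  }
  if (anyDuplicated(vars)) stop("duplicate variable in grid", call. = FALSE)
  if (target %in% c(vars, names(fixed))) {
    stop("target must not appear in the grid or fixed evidence",
         call. = FALSE)
  }
  if (length(intersect(vars, names(fixed)))) {
    stop("grid and fixed evidence overlap", call. = FALSE)
  }
  structure(list(target = target, target_state = target_state,
                 grid = grid, fixed = fixed),
            class = "stressbn_scenario_spec")
}

#' Evidence combinations of a scenario grid
#'
#' Cartesian product of the grid states in declared order: the first
#' (outermost) grid variable varies slowest, the last fastest, matching the
#' nested layout of the published tables.
#'
#' @param spec a [scenario_spec()].
#' @return data frame of evidence combinations, one row per scenario; a
#'   single zero-column row for an empty grid.
#' @export
scenario_grid <- function(spec) {
  stopifnot(inherits(spec, "stressbn_scenario_spec"))
  if (!length(spec$grid)) {
    return(data.frame(row.names = 1)[, 0, drop = FALSE])
  }
  g <- rev(expand.grid(rev(spec$grid), stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE))
  rownames(g) <- NULL
  g
}

#' Posterior sensitivity table over an evidence grid
#'
#' For every grid row, computes 100 * P(target = target_state | row
#' evidence + fixed evidence). Percentages are carried unrounded in the
#' result; rounding to the two-decimal presentation convention happens only
#' in [format_scenario_table()]. Rows whose evidence has zero probability
#' are flagged in `zero_mass` and carry `NA`, never dropped, so the table
#' shape stays predictable.
#'
#' @param bn a `stressbn_bn` containing every spec variable.
#' @param spec a [scenario_spec()].
#' @return a `stressbn_scenario_table`: the grid columns plus
#'   `stressed_pct` (unrounded percentage) and `zero_mass` (logical).
#' @export
sensitivity_table <- function(bn, spec) {
  stopifnot(inherits(spec, "stressbn_scenario_spec"))
  for (v in c(spec$target, names(spec$grid), names(spec$fixed))) {
    if (!v %in% bn$dag$nodes) {
      stop("variable absent from the network: ", v, call. = FALSE)
    }
  }
  grid <- scenario_grid(spec)
  pct <- numeric(nrow(grid))
  zero <- logical(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    ev <- c(as.list(grid[i, , drop = FALSE]), spec$fixed)
    p <- tryCatch(predict_proba(bn, spec$target, spec$target_state, ev),
                  stressbn_zero_evidence_error = function(e) NA_real_)
    if (is.na(p)) zero[i] <- TRUE
    pct[i] <- 100 * p
  }
  out <- cbind(grid, stressed_pct = pct, zero_mass = zero)
  attr(out, "spec") <- spec
  class(out) <- c("stressbn_scenario_table", class(out))
  out
}

#' Signed difference between two scenario rows
#'
#' Difference `comparison - baseline` of the unrounded posterior
#' percentages, in percentage points, reported to one decimal. Computing on
#' unrounded values mirrors the published delta convention (e.g. a drop
#' from 52.77 to 28.56 is reported as 24.2, not 52.8 - 28.6).
#'
#' @param table a [sensitivity_table()] result.
#' @param baseline_row,comparison_row row indices.
#' @return signed difference in percentage points, one decimal.
#' @export
delta_report <- function(table, baseline_row, comparison_row) {
  n <- nrow(table)
  if (baseline_row < 1 || baseline_row > n ||
      comparison_row < 1 || comparison_row > n) {
    stop("row index out of range", call. = FALSE)
  }
  round_half_up(table$stressed_pct[comparison_row] -
                  table$stressed_pct[baseline_row], 1)
}

#' Format a scenario table for presentation
#'
#' @param table a [sensitivity_table()] result.
#' @param digits decimals for the percentage (default 2, the published
#'   convention).
#' @return character vector of aligned text lines.
#' @export
format_scenario_table <- function(table, digits = 2) {
  df <- as.data.frame(table)
  df$stressed_pct <- ifelse(df$zero_mass, "zero-mass",
                            paste0(formatC(round_half_up(df$stressed_pct,
                                                         digits),
                                           format = "f", digits = digits),
                                   "%"))
  df$zero_mass <- NULL
  names(df)[names(df) == "stressed_pct"] <- "Stressed%"
  widths <- pmax(nchar(names(df)),
                 vapply(df, function(x) max(nchar(as.character(x)), 0L),
                        integer(1)))
  fmt_row <- function(cells) {
    paste(mapply(formatC, as.character(cells), width = widths,
                 MoreArgs = list(flag = "-")), collapse = "  ")
  }
  c(fmt_row(names(df)),
    vapply(seq_len(nrow(df)), function(i) fmt_row(df[i, ]), character(1)))
}

#' Preset scenario specifications of the published analyses
#'
#' Named presets reproducing the structure of the published sensitivity
#' tables over the study variables:
#' \describe{
#'   \item{`table4`}{job demand (extremes) by family demand (extremes),
#'     the 2x2 nested demand grid.}
#'   \item{`table4_emotional`}{job demand (extremes) by emotional demand
#'     (extremes).}
#'   \item{`table5`}{job demand (3) by control (2) by colleague support
#'     (3): 18 rows.}
#'   \item{`table5_boss`}{job demand by control by boss support.}
#'   \item{`table6`}{job demand by control by recognition.}
#'   \item{`table7` / `table7_favourable`}{recognition by gender under
#'     fixed adverse (high demand, no control) or favourable (low demand,
#'     control) conditions.}
#'   \item{`table8` / `table8_favourable`}{recognition by age group under
#'     the same fixed conditions.}
#' }
#'
#' @param name preset name.
#' @return a [scenario_spec()].
#' @export
scenario_preset <- function(name = c("table4", "table4_emotional", "table5",
                                     "table5_boss", "table6", "table7",
                                     "table7_favourable", "table8",
                                     "table8_favourable")) {
  name <- match.arg(name)
  sv <- study_variables()
  ext <- function(v) sv[[v]][c(1, length(sv[[v]]))]
  adverse <- list(job_demand = sv$job_demand[1], control = "No")
  favourable <- list(job_demand = sv$job_demand[3], control = "Yes")
  switch(name,
    table4 = scenario_spec(grid = list(job_demand = ext("job_demand"),
                                       family_demand = ext("family_demand"))),
    table4_emotional = scenario_spec(
      grid = list(job_demand = ext("job_demand"),
                  emotional_demand = ext("emotional_demand"))),
    table5 = scenario_spec(grid = list(job_demand = sv$job_demand,
                                       control = sv$control,
                                       colleague_support = sv$colleague_support)),
    table5_boss = scenario_spec(grid = list(job_demand = sv$job_demand,
                                            control = sv$control,
                                            boss_support = sv$boss_support)),
    table6 = scenario_spec(grid = list(job_demand = sv$job_demand,
                                       control = sv$control,
                                       recognition = sv$recognition)),
    table7 = scenario_spec(grid = list(recognition = sv$recognition,
                                       gender = sv$gender),
                           fixed = adverse),
    table7_favourable = scenario_spec(grid = list(recognition = sv$recognition,
                                                  gender = sv$gender),
                                      fixed = favourable),
    table8 = scenario_spec(grid = list(recognition = sv$recognition,
                                       age_group = sv$age_group),
                           fixed = adverse),
    table8_favourable = scenario_spec(grid = list(recognition = sv$recognition,
                                                  age_group = sv$age_group),
                                      fixed = favourable))
}

#' Read a scenario specification from YAML or JSON
#'
#' The file holds fields `target`, `target_state`, `grid` (mapping of
#' variable to state list) and optional `fixed` (mapping of variable to
#' state).
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return a [scenario_spec()].
#' @export
read_scenario_spec <- function(path) {
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  scenario_spec(target = obj$target %||% "stress",
                target_state = obj$target_state %||% "Yes",
                grid = lapply(obj$grid, unlist),
                fixed = lapply(obj$fixed, function(x) unlist(x)[1]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
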