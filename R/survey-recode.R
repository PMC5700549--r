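#' @title Survey recoding: from raw EWCS question codes to study variables
#' @description Helpers that construct the ten categorical study variables
#'   from raw question codes (Q78 symptom flags, Q2a/Q2b, Q30h, Q45d,
#'   Q49a/b, Q54a/c, Q61a/b, Q63a-f, Q89c). All helpers are vectorized,
#'   total on their declared input range, and propagate `NA` (missing /
#'   "No reply") inputs as `NA` outputs.
#' @name survey_recode
NULL

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# round to `digits` decimals, half away from zero (the convention of the
# published percentage tables; base round() would round half to even)
round_half_up <- function(x, digits = 0) round_half_away(x * 10^digits) / 10^digits

check_codes <- function(code, lo, hi, what) {
  bad <- !is.na(code) & (code < lo | code > hi | code != floor(code))
  if (any(bad)) {
    stop(sprintf("%s codes must be integers in %d..%d (got %s)",
                 what, lo, hi, paste(unique(code[bad]), collapse = ", ")),
         call. = FALSE)
  }
}

#' Collapse a 7-point frequency code to three categories
#'
#' Maps the 7-point "all of the time ... never" response scale to the three
#' analysis categories: codes 1-2 to 1 ("All & almost all of the time"),
#' 3-5 to 2 ("Around half of the time"), 6-7 to 3 ("Almost never & never").
#'
#' @param code integer vector of codes in 1..7; `NA` allowed.
#' @return integer vector of categories in 1..3.
#' @export
#' @examples
#' map_frequency7_to3(c(2, 4, 7))
map_frequency7_to3 <- function(code) {
  check_codes(code, 1L, 7L, "7-point frequency")
  c(1L, 1L, 2L, 2L, 2L, 3L, 3L)[code]
}

#' Collapse a 5-point frequency or agreement code to three categories
#'
#' Codes 1-2 map to category 1, 3 to 2, 4-5 to 3. Used for family demands
#' and colleague support ("Always & most of the time" / "Sometimes" /
#' "Rarely & never") and for the agreement scales ("Strongly & tend to
#' agree" / "Neither agree or disagree" / "Tend to & strongly disagree").
#'
#' @param code integer vector of codes in 1..5; `NA` allowed.
#' @return integer vector of categories in 1..3.
#' @export
#' @examples
#' map_frequency5_to3(1:5)
map_frequency5_to3 <- function(code) {
  check_codes(code, 1L, 5L, "5-point")
  c(1L, 1L, 2L, 3L, 3L)[code]
}

#' Derive the stress outcome from the seven psychosomatic symptom flags
#'
#' A respondent is classified as stressed when reporting at least three of
#' the seven health problems (hearing, skin, backache, muscular pain,
#' headache, anxiety, overall fatigue).
#'
#' @param flags either a length-7 binary vector (one respondent) or an
#'   n-by-7 matrix/data frame of 0/1 flags (rows = respondents). `NA` in any
#'   flag makes that respondent's result `NA`.
#' @return character vector of `"Yes"`/`"No"` (or `NA`).
#' @export
#' @examples
#' derive_stress(c(1, 1, 1, 0, 0, 0, 0))
#' derive_stress(rbind(rep(0, 7), rep(1, 7)))
derive_stress <- function(flags) {
  if (is.data.frame(flags)) flags <- as.matrix(flags)
  if (!is.matrix(flags)) {
    if (length(flags) != 7L) stop("expected 7 symptom flags", call. = FALSE)
    flags <- matrix(flags, nrow = 1L)
  }
  if (ncol(flags) != 7L) stop("expected 7 symptom flag columns", call. = FALSE)
  bad <- !is.na(flags) & !(flags %in% c(0, 1))
  if (any(bad)) stop("symptom flags must be 0/1", call. = FALSE)
  ifelse(is.na(rowSums(flags)), NA_character_,
         ifelse(rowSums(flags) >= 3, "Yes", "No"))
}

#' Derive the age group
#'
#' Four groups: younger than 35; 35 to under 45; 45 to 55 inclusive; older
#' than 55 (strict, so age 55 falls in the third group).
#'
#' @param age integer vector of ages in years (>= 15).
#' @return character vector of age-group labels.
#' @export
#' @examples
#' derive_age_group(c(34, 45, 55, 70))
derive_age_group <- function(age) {
  if (any(!is.na(age) & age < 15)) stop("age must be >= 15", call. = FALSE)
  labs <- study_variables()$age_group
  labs[findInterval(age, c(-Inf, 35, 45, 55 + 1e-9))]
}

#' Derive gender from the Q2a code
#' @param code integer vector: 1 = man, 2 = woman.
#' @return character vector of `"Male"`/`"Female"`.
#' @export
derive_gender <- function(code) {
  check_codes(code, 1L, 2L, "gender")
  c("Male", "Female")[code]
}

#' Derive emotional demand from the Q30h 7-point code
#' @param code integer vector in 1..7.
#' @return character vector of 3-category labels.
#' @export
derive_emotional_demand <- function(code) {
  study_variables()$emotional_demand[map_frequency7_to3(code)]
}

#' Derive family demand from the Q45d 5-point code
#' @param code integer vector in 1..5.
#' @return character vector of 3-category labels.
#' @export
derive_family_demand <- function(code) {
  study_variables()$family_demand[map_frequency5_to3(code)]
}

#' Derive job demand as the rounded mean of the two Q49 codes
#'
#' The two 7-point codes (working at very high speed; working to tight
#' deadlines) are averaged, rounded (default: half away from zero), and the
#' rounded mean is collapsed with [map_frequency7_to3()].
#'
#' @param code_a,code_b integer vectors in 1..7.
#' @param rounding `"half_away"` (default) or `"half_even"` (base `round`).
#' @return character vector of 3-category labels.
#' @export
#' @examples
#' derive_job_demand(2, 3)   # mean 2.5 -> 3 -> middle category
derive_job_demand <- function(code_a, code_b, rounding = c("half_away", "half_even")) {
  rounding <- match.arg(rounding)
  check_codes(code_a, 1L, 7L, "Q49a")
  check_codes(code_b, 1L, 7L, "Q49b")
  m <- (code_a + code_b) / 2
  r <- if (rounding == "half_away") round_half_away(m) else round(m)
  study_variables()$job_demand[map_frequency7_to3(as.integer(r))]
}

#' Derive control from the two Q54 yes/no codes
#'
#' Summarizes ability to change the order of work (Q54a) and the speed or
#' rate of work (Q54c) into a single yes/no variable. Under the default
#' `"both_yes"` rule the respondent has control only when both answers are
#' yes; `"any_yes"` requires at least one.
#'
#' @param code_a,code_b integer vectors: 1 = yes, 2 = no.
#' @param rule combination rule, `"both_yes"` (default) or `"any_yes"`.
#' @return character vector of `"Yes"`/`"No"`.
#' @export
derive_control <- function(code_a, code_b, rule = c("both_yes", "any_yes")) {
  rule <- match.arg(rule)
  check_codes(code_a, 1L, 2L, "Q54a")
  check_codes(code_b, 1L, 2L, "Q54c")
  a <- code_a == 1L
  b <- code_b == 1L
  yes <- if (rule == "both_yes") a & b else a | b
  yes[is.na(code_a) | is.na(code_b)] <- NA  # never resolve from one answer
  ifelse(yes, "Yes", "No")
}

#' Derive colleague support from the Q61a 5-point code
#' @param code integer vector in 1..5.
#' @return character vector of 3-category labels.
#' @export
derive_colleague_support <- function(code) {
  study_variables()$colleague_support[map_frequency5_to3(code)]
}

#' Derive boss support as the rounded mean of the seven supervisor items
#'
#' Aggregates Q61b and the six Q63 supervisor items (all 5-point agreement
#' scales, alpha = 0.88 in the source data) by their rounded mean and
#' collapses it to agree / neither / disagree.
#'
#' @param codes length-7 vector or n-by-7 matrix/data frame of codes in 1..5.
#' @param rounding `"half_away"` (default) or `"half_even"`.
#' @return character vector of 3-category labels.
#' @export
#' @examples
#' derive_boss_support(c(2, 3, 3, 3, 3, 3, 3))  # mean 20/7 -> 3 -> neither
derive_boss_support <- function(codes, rounding = c("half_away", "half_even")) {
  rounding <- match.arg(rounding)
  if (is.data.frame(codes)) codes <- as.matrix(codes)
  if (!is.matrix(codes)) {
    if (length(codes) != 7L) stop("expected 7 supervisor item codes", call. = FALSE)
    codes <- matrix(codes, nrow = 1L)
  }
  if (ncol(codes) != 7L) stop("expected 7 supervisor item columns", call. = FALSE)
  check_codes(as.vector(codes), 1L, 5L, "supervisor item")
  m <- rowMeans(codes)
  r <- if (rounding == "half_away") round_half_away(m) else round(m)
  study_variables()$boss_support[map_frequency5_to3(as.integer(r))]
}

#' Derive recognition from the Q89c 5-point agreement code
#' @param code integer vector in 1..5.
#' @return character vector of 3-category labels.
#' @export
derive_recognition <- function(code) {
  study_variables()$recognition[map_frequency5_to3(code)]
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient
#' \eqn{\alpha = k/(k-1)\,(1 - \sum_i \mathrm{var}(x_i)/\mathrm{var}(\sum_i x_i))}
#' with the sample-variance convention (divisor n - 1).
#'
#' @param items numeric matrix or data frame, n records by k >= 2 items,
#'   no missing entries.
#' @return alpha, a unitless value in (-Inf, 1].
#' @export
#' @examples
#' cronbach_alpha(cbind(1:4, 2 * (1:4)))  # parallel items -> 1
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  if (ncol(items) < 2L) stop("need at least 2 items", call. = FALSE)
  if (nrow(items) < 2L) stop("need at least 2 records", call. = FALSE)
  if (anyNA(items)) stop("missing entries not allowed", call. = FALSE)
  k <- ncol(items)
  vt <- stats::var(rowSums(items))
  if (vt == 0) stop("total-score variance is zero; alpha undefined", call. = FALSE)
  k / (k - 1) * (1 - sum(apply(items, 2, stats::var)) / vt)
}

#' Default codebook for the recoding pipeline
#'
#' Houses the configurable recoding choices: the control combination rule,
#' the rounding rule for composite means, and the missing-data policy
#' (`"keep_NR"` keeps "No reply" as an explicit reportable state;
#' `"complete_case"` drops records with any NR among the modelled
#' variables, the convention used before network learning).
#'
#' @param control_rule `"both_yes"` or `"any_yes"`.
#' @param rounding `"half_away"` or `"half_even"`.
#' @param policy `"keep_NR"` or `"complete_case"`.
#' @return an object of class `stressbn_codebook`.
#' @export
default_codebook <- function(control_rule = c("both_yes", "any_yes"),
                             rounding = c("half_away", "half_even"),
                             policy = c("keep_NR", "complete_case")) {
  structure(list(control_rule = match.arg(control_rule),
                 rounding = match.arg(rounding),
                 policy = match.arg(policy)),
            class = "stressbn_codebook")
}

raw_columns <- function() {
  c("q2a", "q2b", "q30h", "q45d", "q49a", "q49b", "q54a", "q54c",
    "q61a", "q61b", paste0("q63", letters[1:6]), paste0("q78", letters[1:7]),
    "q89c")
}

#' Recode a raw survey table into the ten study variables
#'
#' Applies the full variable-construction scheme to a table of raw question
#' codes and returns one recoded record per input row together with a log of
#' "No reply" counts per study variable. Under the `"complete_case"` policy,
#' records with NR in any study variable are dropped from the returned data
#' (the log still counts them).
#'
#' @param raw data frame with the question-code columns `q2a`, `q2b`,
#'   `q30h`, `q45d`, `q49a`, `q49b`, `q54a`, `q54c`, `q61a`, `q61b`,
#'   `q63a`..`q63f`, `q78a`..`q78g`, `q89c`; missing values as `NA`.
#' @param codebook a [default_codebook()] object.
#' @return list with `data` (data frame of factors; levels are the declared
#'   state labels plus `"NR"` under `"keep_NR"`) and `log` (data frame of NR
#'   counts per variable, plus the number of dropped records as an
#'   attribute `dropped`).
#' @export
recode_dataset <- function(raw, codebook = default_codebook()) {
  stopifnot(inherits(codebook, "stressbn_codebook"))
  missing_cols <- setdiff(raw_columns(), names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  sv <- study_variables()
  n <- nrow(raw)
  rec <- data.frame(row.names = seq_len(n))
  if (n == 0L) {
    rec <- as.data.frame(stats::setNames(
      lapply(names(sv), function(v) factor(character(0), levels = sv[[v]])),
      names(sv)))
  } else {
    rec$gender <- derive_gender(raw$q2a)
    rec$age_group <- derive_age_group(raw$q2b)
    rec$emotional_demand <- derive_emotional_demand(raw$q30h)
    rec$family_demand <- derive_family_demand(raw$q45d)
    rec$job_demand <- derive_job_demand(raw$q49a, raw$q49b, codebook$rounding)
    rec$control <- derive_control(raw$q54a, raw$q54c, codebook$control_rule)
    rec$colleague_support <- derive_colleague_support(raw$q61a)
    rec$boss_support <- derive_boss_support(
      raw[, c("q61b", paste0("q63", letters[1:6]))], codebook$rounding)
    rec$recognition <- derive_recognition(raw$q89c)
    rec$stress <- derive_stress(raw[, paste0("q78", letters[1:7])])
    rec <- rec[, names(sv)]
  }
  log <- data.frame(variable = names(sv),
                    n_nr = vapply(rec, function(x) sum(is.na(x)), integer(1)),
                    row.names = NULL, stringsAsFactors = FALSE)
  dropped <- 0L
  if (codebook$policy == "complete_case") {
    keep <- stats::complete.cases(rec)
    dropped <- sum(!keep)
    rec <- rec[keep, , drop = FALSE]
    for (v in names(sv)) rec[[v]] <- factor(rec[[v]], levels = sv[[v]])
  } else {
    for (v in names(sv)) {
      x <- as.character(rec[[v]])
      x[is.na(x)] <- "NR"
      rec[[v]] <- factor(x, levels = c(sv[[v]], "NR"))
    }
  }
  rownames(rec) <- NULL
  attr(log, "dropped") <- dropped
  list(data = rec, log = log)
}

#' Drop records with any "No reply" state
#'
#' Complete-case filter applied before network learning: removes every
#' record carrying an `"NR"` state (or `NA`) in any of the given columns and
#' drops the `"NR"` factor level.
#'
#' @param data recoded data frame of factors.
#' @param variables columns to screen; default all.
#' @return filtered data frame whose factor levels exclude `"NR"`.
#' @export
complete_cases_only <- function(data, variables = names(data)) {
  ok <- rep(TRUE, nrow(data))
  for (v in variables) {
    x <- data[[v]]
    ok <- ok & !is.na(x) & as.character(x) != "NR"
  }
  out <- data[ok, , drop = FALSE]
  for (v in names(out)) {
    if (is.factor(out[[v]])) {
      out[[v]] <- factor(out[[v]], levels = setdiff(levels(out[[v]]), "NR"))
    }
  }
  rownames(out) <- NULL
  out
}

#' Per-variable frequency table with rounded percentages
#'
#' Counts and percentages per state for each study variable, in the layout
#' of the published frequency table: percentages are computed over all
#' records (including "No reply") and rounded half away from zero.
#'
#' @param data data frame of factors (recoded records).
#' @param digits decimal places for the percentage (default 1, the published
#'   one-decimal convention).
#' @return data frame with columns `variable`, `state`, `n`, `pct`.
#' @export
frequency_table <- function(data, digits = 1) {
  n <- nrow(data)
  out <- do.call(rbind, lapply(names(data), function(v) {
    x <- data[[v]]
    if (!is.factor(x)) x <- factor(x)
    cnt <- table(x)
    cnt <- cnt[cnt > 0 | names(cnt) %in% levels(x)]
    data.frame(variable = v, state = names(cnt), n = as.integer(cnt),
               pct = if (n > 0) round_half_up(100 * as.integer(cnt) / n, digits)
                     else rep(NA_real_, length(cnt)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
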