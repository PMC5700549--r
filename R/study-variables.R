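#' State spaces of the ten study variables
#'
#' The occupational-stress model uses ten categorical variables arranged in
#' five groups: demographic (gender, age group), demands (emotional, family
#' and job demand), control, social support (colleagues and boss) and
#' recognition, plus the binary stress outcome derived from psychosomatic
#' health complaints. State labels follow the published frequency-table
#' wording so that scenario tables can be laid out with the same row labels.
#'
#' @return Named list; one ordered character vector of state labels per
#'   variable. The first label of every demand/support/recognition variable
#'   is its most adverse (respectively most supportive) end, matching the
#'   1..3 coding used by the recode helpers.
#' @export
#' @examples
#' names(study_variables())
#' study_variables()$job_demand
study_variables <- function() {
  freq3 <- c("All & almost all of the time", "Around half of the time",
             "Almost never & never")
  often3 <- c("Always & most of the time", "Sometimes", "Rarely & never")
  agree3 <- c("Strongly & tend to agree", "Neither agree or disagree",
              "Tend to & strongly disagree")
  list(
    gender            = c("Male", "Female"),
    age_group         = c("<35", "Between 35 and 45", "Between 45 and 55", ">55"),
    emotional_demand  = freq3,
    family_demand     = often3,
    job_demand        = freq3,
    control           = c("Yes", "No"),
    colleague_support = often3,
    boss_support      = agree3,
    recognition       = agree3,
    stress            = c("Yes", "No")
  )
}

#' Published marginal frequencies of the study variables
#'
#' Per-state record counts for the ten study variables in the 2,211-record
#' healthcare-worker subset of the 6th European Working Conditions Survey,
#' as printed in the study's frequency table, including the "No reply" (NR)
#' rows. These counts calibrate the synthetic-data generator and back the
#' exact percentage checks.
#'
#' @return A data frame with columns `variable`, `state`, `n`. States are in
#'   declared order (see [study_variables()]); an `"NR"` row is present where
#'   the published table reports one.
#' @export
#' @examples
#' subset(study_margins(), variable == "stress")
study_margins <- function() {
  sv <- study_variables()
  counts <- list(
    gender            = c(465, 1745, NR = 1),
    age_group         = c(590, 533, 644, 444),
    emotional_demand  = c(565, 832, 811, NR = 3),
    family_demand     = c(443, 691, 1055, NR = 22),
    job_demand        = c(433, 898, 870, NR = 10),
    control           = c(1518, 659, NR = 34),
    colleague_support = c(1739, 238, 102, NR = 132),
    boss_support      = c(1314, 498, 137, NR = 262),
    recognition       = c(578, 1240, 373, NR = 20),
    stress            = c(814, 1397)
  )
  out <- do.call(rbind, lapply(names(counts), function(v) {
    k <- counts[[v]]
    states <- sv[[v]]
    labs <- c(states[seq_len(length(k) - sum(names(k) == "NR"))],
              if (any(names(k) == "NR")) "NR")
    data.frame(variable = v, state = labs, n = unname(k),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Root marginals over the modelled (non-NR) states, renormalized.
# Used as the generator defaults.
study_root_marginals <- function() {
  m <- study_margins()
  m <- m[m$state != "NR" & m$variable != "stress", , drop = FALSE]
  sv <- study_variables()
  out <- lapply(split(m, factor(m$variable, levels = unique(m$variable))),
                function(d) stats::setNames(d$n / sum(d$n), d$state))
  out[setdiff(names(sv), "stress")]
}

# Published NR ("No reply") rates per variable, as fractions of 2,211.
study_missing_rates <- function() {
  m <- study_margins()
  tot <- sum(m$n[m$variable == "stress"])
  nr <- m[m$state == "NR", , drop = FALSE]
  rates <- stats::setNames(rep(0, length(study_variables())),
                           names(study_variables()))
  rates[nr$variable] <- nr$n / tot
  rates
}

# Published stress prevalence (814 of 2,211), the calibration target for the
# generator intercept.
study_stress_prevalence <- function() 814 / 2211
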