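#' @title Calibrated synthetic survey generator
#' @description Generates survey-like datasets with the state spaces and
#'   marginal frequencies of the published 2,211-record healthcare subset
#'   of the 6th EWCS, "No reply" missingness at the published rates, and a
#'   known monotone logistic stress mechanism — so that every pipeline
#'   stage (recoding, learning, inference, scenarios, validation) is
#'   testable without the restricted microdata.
#' @name synthetic_data
NULL

# Default per-level log-odds weights of the stress mechanism, one vector
# per explanatory variable, in declared state order. Adverse levels (higher
# demands, no control, lower support and recognition, female, mid-career
# age) carry the larger weights, so the qualitative orderings reported for
# the study variables hold in the ground truth by construction; recognition
# and boss support carry the strongest effects, colleague support the
# weakest of the support block.
default_stress_weights <- function() {
  list(
    gender            = c(0, 0.35),
    age_group         = c(0, 0.45, 0.40, 0.10),
    emotional_demand  = c(0.90, 0.35, 0),
    family_demand     = c(0.55, 0.25, 0),
    job_demand        = c(0.85, 0.35, 0),
    control           = c(0, 0.55),
    colleague_support = c(0, 0.25, 0.50),
    boss_support      = c(0, 0.45, 0.95),
    recognition       = c(0, 0.50, 1.05)
  )
}

#' Configuration of the synthetic-data generator
#'
#' The defaults are the study conditions: root marginals equal to the
#' published per-state counts renormalized over the non-NR states,
#' missingness ("No reply") rates equal to the published NR percentages,
#' the published sample size, and a stress prevalence target of 814/2211.
#'
#' @param n sample size (default 2211, the published subset size).
#' @param marginals named list of root marginal probability vectors for the
#'   nine explanatory variables (each summing to 1).
#' @param weights named list of per-level log-odds weight vectors for the
#'   stress mechanism; `weight_scale` multiplies all of them (signal
#'   strength dial for simulation studies, default 1).
#' @param intercept intercept of the logistic stress mechanism; `NULL`
#'   (default) means "calibrate to `stress_target` at build time".
#' @param stress_target marginal stress prevalence to calibrate the
#'   intercept to (default 814/2211).
#' @param missing_rates named per-variable NR rates in `[0, 1)`.
#' @param weight_scale numeric multiplier on all weights.
#' @return object of class `stressbn_generator_config`.
#' @export
generator_config <- function(n = 2211,
                             marginals = study_root_marginals(),
                             weights = default_stress_weights(),
                             intercept = NULL,
                             stress_target = study_stress_prevalence(),
                             missing_rates = study_missing_rates(),
                             weight_scale = 1) {
  sv <- study_variables()
  expl <- setdiff(names(sv), "stress")
  if (!setequal(names(marginals), expl)) {
    stop("marginals must cover exactly the nine explanatory variables",
         call. = FALSE)
  }
  for (v in expl) {
    if (length(marginals[[v]]) != length(sv[[v]])) {
      stop("marginal for ", v, " must have ", length(sv[[v]]), " states",
           call. = FALSE)
    }
    if (abs(sum(marginals[[v]]) - 1) > 1e-9) {
      stop("marginal for ", v, " does not sum to 1", call. = FALSE)
    }
    if (length(weights[[v]]) != length(sv[[v]])) {
      stop("weights for ", v, " must have ", length(sv[[v]]), " entries",
           call. = FALSE)
    }
  }
  if (n < 1) stop("sample size must be >= 1", call. = FALSE)
  if (!is.null(stress_target) &&
      (stress_target <= 0 || stress_target >= 1)) {
    stop("stress_target must lie in (0, 1)", call. = FALSE)
  }
  bad <- names(missing_rates)[missing_rates < 0 | missing_rates >= 1]
  if (length(bad)) stop("missing rates must lie in [0, 1): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  structure(list(n = n, marginals = marginals[expl],
                 weights = lapply(weights[expl], function(w) w * weight_scale),
                 intercept = intercept, stress_target = stress_target,
                 missing_rates = missing_rates),
            class = "stressbn_generator_config")
}

# linear predictor of the stress mechanism for every root configuration,
# plus the root-configuration probabilities (roots are independent)
stress_mechanism_grid <- function(config) {
  expl <- names(config$marginals)
  sizes <- vapply(config$marginals, length, integer(1))
  grid <- rev(expand.grid(rev(lapply(sizes, seq_len)),
                          KEEP.OUT.ATTRS = FALSE))
  names(grid) <- expl
  lp <- rep(0, nrow(grid))
  pr <- rep(1, nrow(grid))
  for (v in expl) {
    lp <- lp + config$weights[[v]][grid[[v]]]
    pr <- pr * config$marginals[[v]][grid[[v]]]
  }
  list(grid = grid, lp = lp, prob = unname(pr))
}

#' Build the ground-truth network of a generator configuration
#'
#' The nine explanatory variables are independent root nodes carrying the
#' configured marginals; stress is their common child with
#' P(stress = Yes | parents) = plogis(intercept + sum of the parents'
#' level weights). When the configured intercept is `NULL` it is first
#' calibrated to the configured stress prevalence via
#' [calibrate_intercept()].
#'
#' @param config a [generator_config()].
#' @return a `stressbn_ground_truth`: list with the realized `bn`, the
#'   `config` (intercept filled in) and the exact model-implied
#'   `stress_marginal`.
#' @export
build_ground_truth <- function(config) {
  stopifnot(inherits(config, "stressbn_generator_config"))
  if (is.null(config$intercept)) {
    return(calibrate_intercept(config, config$stress_target))
  }
  sv <- study_variables()
  expl <- names(config$marginals)
  mech <- stress_mechanism_grid(config)
  p_yes <- stats::plogis(config$intercept + mech$lp)
  sizes <- vapply(config$marginals, length, integer(1))
  # stress CPT: child-first array; parent configs in column-major order
  # (first parent fastest), so rebuild the linear predictor in that order
  cm_grid <- expand.grid(lapply(sizes, seq_len), KEEP.OUT.ATTRS = FALSE)
  lp_cm <- rep(0, nrow(cm_grid))
  for (v in expl) lp_cm <- lp_cm + config$weights[[v]][cm_grid[[v]]]
  p_cm <- stats::plogis(config$intercept + lp_cm)
  stress_cpt <- array(rbind(p_cm, 1 - p_cm), dim = c(2L, sizes))
  cpts <- c(lapply(config$marginals, unname), list(stress = stress_cpt))
  dag <- new_dag(c(expl, "stress"), cbind(from = expl, to = "stress"))
  bn <- new_bn(dag, sv[c(expl, "stress")], cpts)
  structure(list(bn = bn, config = config,
                 stress_marginal = sum(mech$prob * p_yes)),
            class = "stressbn_ground_truth")
}

#' Calibrate the stress-mechanism intercept to a target prevalence
#'
#' Bisection on the intercept until the exact model-implied marginal
#' P(stress = Yes) — computed by enumeration over all root configurations
#' weighted by the root marginals — is within `tolerance` of `target`. The
#' marginal is strictly increasing in the intercept, so bisection
#' converges.
#'
#' @param config a [generator_config()] (any configured intercept is
#'   ignored and re-derived).
#' @param target prevalence in (0, 1).
#' @param tolerance absolute tolerance on the implied marginal
#'   (default 1e-6).
#' @return a `stressbn_ground_truth` with the calibrated intercept.
#' @export
calibrate_intercept <- function(config, target = config$stress_target,
                                tolerance = 1e-6) {
  stopifnot(inherits(config, "stressbn_generator_config"))
  if (is.null(target) || target <= 0 || target >= 1) {
    stop("target prevalence must lie in (0, 1)", call. = FALSE)
  }
  mech <- stress_mechanism_grid(config)
  implied <- function(b) sum(mech$prob * stats::plogis(b + mech$lp))
  lo <- -40
  hi <- 40
  if (implied(lo) > target || implied(hi) < target) {
    stop(sprintf("target %.4f unreachable; achievable range [%.4f, %.4f]",
                 target, implied(lo), implied(hi)), call. = FALSE)
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    val <- implied(mid)
    if (abs(val - target) <= tolerance) break
    if (val < target) lo <- mid else hi <- mid
  }
  config$intercept <- mid
  build_ground_truth(config)
}

#' Draw records from a Bayesian network by ancestral sampling
#'
#' Samples each node after its parents along a topological order;
#' reproducible given the seed.
#'
#' @param bn a `stressbn_bn` (or a `stressbn_ground_truth`, whose network
#'   is used).
#' @param n number of records.
#' @param seed integer seed.
#' @return data frame of factors, one column per node in network order.
#' @export
ancestral_sample <- function(bn, n, seed = 1) {
  if (inherits(bn, "stressbn_ground_truth")) bn <- bn$bn
  stopifnot(inherits(bn, "stressbn_bn"), n >= 1)
  ord <- topological_order(bn$dag$nodes, dag_edges(bn$dag))
  out <- vector("list", length(bn$dag$nodes))
  names(out) <- bn$dag$nodes
  with_seed(seed, {
    for (v in ord) {
      cpt <- bn$cpts[[v]]
      sc <- length(bn$variables[[v]])
      if (!length(cpt$parents)) {
        code <- sample.int(sc, n, replace = TRUE, prob = as.vector(cpt$prob))
      } else {
        sizes <- vapply(bn$variables[cpt$parents], length, integer(1))
        cfg <- rep(0L, n)
        mult <- 1L
        for (k in seq_along(cpt$parents)) {
          cfg <- cfg + (out[[cpt$parents[k]]] - 1L) * mult
          mult <- mult * sizes[k]
        }
        cum <- apply(matrix(cpt$prob, nrow = sc), 2, cumsum)
        u <- stats::runif(n)
        code <- rowSums(u > t(cum)[cfg + 1L, , drop = FALSE]) + 1L
      }
      out[[v]] <- code
    }
  })
  as.data.frame(lapply(stats::setNames(bn$dag$nodes, bn$dag$nodes),
                       function(v) {
    factor(bn$variables[[v]][out[[v]]], levels = bn$variables[[v]])
  }))
}

#' Inject "No reply" missingness completely at random
#'
#' Independently per cell, replaces the value with the explicit `"NR"`
#' state at the variable's rate.
#'
#' @param data data frame of factors.
#' @param rates named per-variable rates in `[0, 1)`; variables without an
#'   entry are untouched.
#' @param seed integer seed.
#' @return data frame whose affected columns gain an `"NR"` level.
#' @export
inject_missing <- function(data, rates = study_missing_rates(), seed = 1) {
  bad <- names(rates)[rates < 0 | rates >= 1]
  if (length(bad)) stop("rates must lie in [0, 1): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  with_seed(seed, {
    for (v in intersect(names(rates), names(data))) {
      if (rates[[v]] == 0) next
      x <- as.character(data[[v]])
      hit <- stats::runif(length(x)) < rates[[v]]
      x[hit] <- "NR"
      data[[v]] <- factor(x, levels = c(levels(data[[v]]), "NR"))
    }
  })
  data
}

#' Map a recoded table back to raw question codes
#'
#' Inverse of the recoding scheme, using a fixed representative raw code
#' per recoded state (e.g. the middle job-demand category becomes
#' Q49a = Q49b = 4). Recoding the result with [recode_dataset()]
#' reproduces the input exactly, which lets synthetic recoded data
#' exercise the survey front end end-to-end. `"NR"` states become `NA`
#' raw codes.
#'
#' @param data recoded data frame of factors (ten study variables).
#' @return data frame with the raw question-code columns.
#' @export
raw_from_recoded <- function(data) {
  lev <- function(v) as.integer(factor(as.character(data[[v]]),
                                       levels = study_variables()[[v]]))
  pick <- function(codes, idx) codes[idx]
  n <- nrow(data)
  raw <- data.frame(row.names = seq_len(n))
  raw$q2a <- pick(c(1L, 2L), lev("gender"))
  raw$q2b <- pick(c(30L, 40L, 50L, 60L), lev("age_group"))
  raw$q30h <- pick(c(2L, 4L, 7L), lev("emotional_demand"))
  raw$q45d <- pick(c(1L, 3L, 5L), lev("family_demand"))
  raw$q49a <- pick(c(2L, 4L, 7L), lev("job_demand"))
  raw$q49b <- raw$q49a
  ctrl <- lev("control")
  raw$q54a <- pick(c(1L, 2L), ctrl)
  raw$q54c <- raw$q54a
  raw$q61a <- pick(c(1L, 3L, 5L), lev("colleague_support"))
  boss <- pick(c(1L, 3L, 5L), lev("boss_support"))
  raw$q61b <- boss
  for (s in letters[1:6]) raw[[paste0("q63", s)]] <- boss
  stress_yes <- as.character(data$stress) == "Yes"
  stress_yes[as.character(data$stress) == "NR"] <- NA
  for (j in 1:7) {
    raw[[paste0("q78", letters[j])]] <- ifelse(stress_yes & j <= 3, 1L,
                                               ifelse(is.na(stress_yes),
                                                      NA_integer_, 0L))
  }
  raw$q89c <- pick(c(1L, 3L, 5L), lev("recognition"))
  rownames(raw) <- NULL
  raw
}
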