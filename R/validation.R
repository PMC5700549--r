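#' @title Cross-validated ROC/AUC evaluation
#' @description Evaluates the network as a probabilistic stress classifier:
#'   k-fold cross-validation (plain random folds of near-equal size),
#'   pooled out-of-fold predictions, ROC curve by threshold sweep and AUC
#'   by both the trapezoid rule and the pair-ranking (Mann-Whitney)
#'   statistic, which are asserted identical.
#' @name validation
NULL

#' Random k-fold partition
#'
#' Seeded uniform random permutation split into k blocks whose sizes differ
#' by at most one; reproducible given the seed.
#'
#' @param n number of records (`n >= k`).
#' @param k number of folds (`k >= 2`).
#' @param seed integer seed.
#' @return integer vector of fold ids in `1..k`, one per record.
#' @export
#' @examples
#' table(kfold_partition(2211, 10, seed = 1))
kfold_partition <- function(n, k, seed = 1) {
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (k > n) stop("k must not exceed n", call. = FALSE)
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  fold <- integer(n)
  fold[with_seed(seed, sample.int(n))] <- rep(seq_len(k), times = sizes)
  fold
}

#' Cross-validated out-of-fold stress predictions
#'
#' For each fold, a network is learned on the other k - 1 folds (by
#' default: structure by [hill_climb()] on that training set, then CPTs
#' with the given pseudocount) and every held-out record is scored with
#' P(target = target_state | all its other variables). Pooled over folds,
#' every record is scored exactly once by a model not trained on it.
#'
#' @param data complete-case data frame of factors including the target.
#' @param target,target_state target variable and its positive state.
#' @param k number of folds (default 10).
#' @param seed seed for the fold partition and structure-search restarts.
#' @param structure `"per_fold"` (default: relearn the DAG on each training
#'   set) or `"fixed"` (use `dag` throughout, parameters only).
#' @param dag fixed DAG for `structure = "fixed"`.
#' @param score,ess,restarts,blacklist,max_parents passed to [hill_climb()].
#' @param pseudocount CPT smoothing for the fitted networks (default 1,
#'   which keeps every evidence configuration strictly positive).
#' @param variables optional state spaces (default: factor levels).
#' @return data frame with one row per record: `index`, `fold`, `score`
#'   (predicted probability) and `label` (1 if the record's target equals
#'   `target_state`).
#' @export
cross_validate <- function(data, target = "stress", target_state = "Yes",
                           k = 10, seed = 1,
                           structure = c("per_fold", "fixed"), dag = NULL,
                           score = "bic", ess = 1, restarts = 0,
                           blacklist = NULL, max_parents = Inf,
                           pseudocount = 1, variables = NULL) {
  structure <- match.arg(structure)
  if (!target %in% names(data)) stop("target column absent", call. = FALSE)
  if (structure == "fixed" && is.null(dag)) {
    stop("structure = 'fixed' needs a dag", call. = FALSE)
  }
  if (is.null(variables)) {
    variables <- lapply(data, function(x) {
      if (is.factor(x)) levels(x) else sort(unique(as.character(x)))
    })
  }
  n <- nrow(data)
  fold <- kfold_partition(n, k, seed)
  scores <- numeric(n)
  for (f in seq_len(k)) {
    train <- data[fold != f, , drop = FALSE]
    test <- data[fold == f, , drop = FALSE]
    if (length(unique(as.character(train[[target]]))) < 2) {
      warning("fold ", f, ": single-class training target; ",
              "proceeding with smoothed CPTs")
    }
    fdag <- if (structure == "fixed") dag else {
      hill_climb(train, score = score, ess = ess, restarts = restarts,
                 seed = seed + f, blacklist = blacklist,
                 max_parents = max_parents, variables = variables)
    }
    bn <- fit_parameters(fdag, train, pseudocount = pseudocount,
                         variables = variables)
    scores[fold == f] <- predict_proba_batch(bn, target, target_state, test)
  }
  data.frame(index = seq_len(n), fold = fold, score = scores,
             label = as.integer(as.character(data[[target]]) == target_state))
}

#' ROC curve points by threshold sweep
#'
#' Sweeps the unique scores in descending order as classification
#' thresholds (predict positive when score >= threshold) and returns the
#' (false-positive-rate, true-positive-rate) staircase from (0, 0) to
#' (1, 1).
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 (or logical) class labels; both classes required.
#' @return data frame with columns `threshold`, `fpr`, `tpr`; the first row
#'   is the (0, 0) endpoint (threshold `Inf`).
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) stop("length mismatch", call. = FALSE)
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  if (np == 0 || nn == 0) {
    stop("ROC undefined: need both a positive and a negative label",
         call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l)
  fp <- cumsum(1 - l)
  last <- !duplicated(grp, fromLast = TRUE)
  data.frame(threshold = c(Inf, s[last]),
             fpr = c(0, fp[last] / nn),
             tpr = c(0, tp[last] / np))
}

#' Area under the ROC curve
#'
#' Computed two ways and asserted equal to 1e-12: the trapezoid rule over
#' the [roc_points()] staircase, and the pair-ranking (Mann-Whitney)
#' statistic — the fraction of positive-negative pairs ordered correctly,
#' ties counted one half.
#'
#' @inheritParams roc_points
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
auc <- function(scores, labels) {
  pts <- roc_points(scores, labels)
  trap <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                 utils::tail(pts$tpr, -1)) / 2)
  labels <- as.integer(as.logical(labels))
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  r <- rank(scores)  # average ranks: ties count one half
  rank_stat <- (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
  if (abs(trap - rank_stat) > 1e-12) {
    stop("internal inconsistency: trapezoid and rank AUC differ by ",
         format(abs(trap - rank_stat)), call. = FALSE)
  }
  trap
}
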