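#' @title Exact inference by variable elimination
#' @description Posterior queries P(query | evidence) on a discrete
#'   Bayesian network, via variable elimination with a min-degree
#'   elimination order, plus a brute-force enumeration oracle used for
#'   testing. Evidence with zero probability raises a distinct error
#'   condition (`stressbn_zero_evidence_error`) rather than returning a
#'   silent fallback.
#' @name inference
NULL

stop_zero_evidence <- function(evidence) {
  stop(structure(class = c("stressbn_zero_evidence_error", "error",
                           "condition"),
                 list(message = paste0(
                        "evidence has zero probability: ",
                        paste(names(evidence), unlist(evidence),
                              sep = "=", collapse = ", ")),
                      call = NULL)))
}

check_evidence <- function(bn, evidence) {
  evidence <- as.list(evidence)
  for (v in names(evidence)) {
    if (!v %in% bn$dag$nodes) stop("unknown evidence variable: ", v,
                                   call. = FALSE)
    if (!evidence[[v]] %in% bn$variables[[v]]) {
      stop("invalid state '", evidence[[v]], "' for variable ", v,
           call. = FALSE)
    }
  }
  evidence
}

# factors: list(vars = character(), prob = array dim = state counts)
cpt_as_factor <- function(bn, v) {
  cpt <- bn$cpts[[v]]
  list(vars = c(v, cpt$parents), prob = cpt$prob)
}

factor_reduce <- function(f, var, state) {
  i <- match(var, f$vars)
  if (is.na(i)) return(f)
  args <- rep(list(TRUE), length(f$vars))
  args[[i]] <- state
  a <- do.call(`[`, c(list(f$prob), args, list(drop = FALSE)))
  d <- dim(a)[-i]
  dn <- dimnames(f$prob)[-i]
  vars <- f$vars[-i]
  if (!length(vars)) return(list(vars = character(0), prob = as.numeric(a)))
  list(vars = vars, prob = array(a, dim = d, dimnames = dn))
}

expand_factor_to <- function(f, uv, spaces) {
  a <- f$prob
  vars <- f$vars
  for (v in setdiff(uv, vars)) {
    k <- length(spaces[[v]])
    a <- array(rep(as.vector(a), k), dim = c(dim(a), k),
               dimnames = c(dimnames(a), stats::setNames(list(spaces[[v]]), v)))
    vars <- c(vars, v)
  }
  aperm(a, match(uv, vars))
}

factor_multiply <- function(f, g, spaces) {
  if (!length(f$vars)) return(list(vars = g$vars, prob = g$prob * f$prob))
  if (!length(g$vars)) return(list(vars = f$vars, prob = f$prob * g$prob))
  uv <- union(f$vars, g$vars)
  list(vars = uv, prob = expand_factor_to(f, uv, spaces) *
         expand_factor_to(g, uv, spaces))
}

factor_marginalize <- function(f, var) {
  i <- match(var, f$vars)
  if (is.na(i)) return(f)
  if (length(f$vars) == 1L) {
    return(list(vars = character(0), prob = sum(f$prob)))
  }
  keep <- seq_along(f$vars)[-i]
  a <- apply(f$prob, keep, sum)
  dn <- dimnames(f$prob)[-i]
  list(vars = f$vars[-i],
       prob = array(a, dim = dim(f$prob)[-i], dimnames = dn))
}

# min-degree elimination order over the interaction graph of factor
# scopes; ties broken alphabetically by variable name
min_degree_order <- function(factors, elim) {
  order <- character(0)
  scopes <- lapply(factors, `[[`, "vars")
  remaining <- sort(elim)
  while (length(remaining)) {
    nb <- lapply(remaining, function(v) {
      u <- unique(unlist(scopes[vapply(scopes, function(s) v %in% s,
                                       logical(1))]))
      setdiff(u, v)
    })
    deg <- vapply(nb, length, integer(1))
    v <- remaining[which.min(deg)]  # which.min takes the first tie (sorted)
    vn <- nb[[match(v, remaining)]]
    scopes <- scopes[!vapply(scopes, function(s) v %in% s, logical(1))]
    scopes <- c(scopes, list(vn))
    order <- c(order, v)
    remaining <- setdiff(remaining, v)
  }
  order
}

#' Exact posterior by variable elimination
#'
#' Computes P(query | evidence) exactly: CPT factors are restricted to the
#' evidence, all other non-query variables are summed out along a
#' min-degree elimination order (deterministic alphabetical tie-break), and
#' the result is normalized.
#'
#' @param bn a `stressbn_bn`.
#' @param query name of the query variable (must not be in the evidence).
#' @param evidence named list/vector of observed states, possibly empty.
#' @return a `stressbn_posterior`: named probability vector over the query
#'   states, summing to 1.
#' @export
#' @examples
#' bn <- new_bn(new_dag(c("A", "B"), rbind(c("A", "B"))),
#'              list(A = c("y", "n"), B = c("y", "n")),
#'              list(A = c(0.5, 0.5), B = matrix(c(0.8, 0.2, 0.1, 0.9), 2)))
#' variable_elimination(bn, "A", list(B = "y"))
variable_elimination <- function(bn, query, evidence = list()) {
  evidence <- check_evidence(bn, evidence)
  if (!query %in% bn$dag$nodes) stop("unknown query variable: ", query,
                                     call. = FALSE)
  if (query %in% names(evidence)) {
    stop("query variable must not appear in the evidence", call. = FALSE)
  }
  factors <- lapply(bn$dag$nodes, function(v) cpt_as_factor(bn, v))
  for (v in names(evidence)) {
    factors <- lapply(factors, factor_reduce, var = v,
                      state = evidence[[v]])
  }
  elim <- setdiff(bn$dag$nodes, c(query, names(evidence)))
  for (v in min_degree_order(factors, elim)) {
    involved <- vapply(factors, function(f) v %in% f$vars, logical(1))
    prod_f <- Reduce(function(a, b) factor_multiply(a, b, bn$variables),
                     factors[involved])
    factors <- c(factors[!involved], list(factor_marginalize(prod_f, v)))
  }
  res <- Reduce(function(a, b) factor_multiply(a, b, bn$variables), factors)
  p <- as.vector(res$prob)
  total <- sum(p)
  if (total <= 0) stop_zero_evidence(evidence)
  structure(stats::setNames(p / total, bn$variables[[query]]),
            variable = query, class = "stressbn_posterior")
}

#' @export
print.stressbn_posterior <- function(x, ...) {
  cat("Posterior of", attr(x, "variable"), "\n")
  print(round(unclass(x), 6))
  invisible(x)
}

#' Enumerate the full joint distribution
#'
#' Exhaustive table of every complete assignment and its probability under
#' the factorization; the testing oracle behind [posterior_oracle()].
#'
#' @param bn a `stressbn_bn`.
#' @param max_cells guard on the joint table size (default 1e6).
#' @return data frame: one factor column per node plus a `prob` column
#'   summing to 1.
#' @export
enumerate_joint <- function(bn, max_cells = 1e6) {
  sizes <- vapply(bn$variables, length, integer(1))
  if (prod(sizes) > max_cells) {
    stop("joint state space too large (", prod(sizes), " cells)",
         call. = FALSE)
  }
  grid <- rev(expand.grid(rev(bn$variables), stringsAsFactors = TRUE))
  prob <- rep(1, nrow(grid))
  for (v in bn$dag$nodes) {
    cpt <- bn$cpts[[v]]
    fam <- c(v, cpt$parents)
    idx <- as.integer(grid[[fam[1]]])
    mult <- length(bn$variables[[fam[1]]])
    for (p in cpt$parents) {
      idx <- idx + (as.integer(grid[[p]]) - 1L) * mult
      mult <- mult * length(bn$variables[[p]])
    }
    prob <- prob * as.vector(cpt$prob)[idx]
  }
  cbind(grid, prob = prob)
}

#' Brute-force posterior oracle
#'
#' Filters the enumerated joint by the evidence, marginalizes to the query
#' and renormalizes. Exponential in the number of variables; exists as an
#' independent correctness oracle for [variable_elimination()].
#'
#' @inheritParams variable_elimination
#' @return a `stressbn_posterior`.
#' @export
posterior_oracle <- function(bn, query, evidence = list()) {
  evidence <- check_evidence(bn, evidence)
  if (query %in% names(evidence)) {
    stop("query variable must not appear in the evidence", call. = FALSE)
  }
  joint <- enumerate_joint(bn)
  keep <- rep(TRUE, nrow(joint))
  for (v in names(evidence)) keep <- keep & joint[[v]] == evidence[[v]]
  joint <- joint[keep, , drop = FALSE]
  mass <- sum(joint$prob)
  if (mass <= 0) stop_zero_evidence(evidence)
  p <- vapply(bn$variables[[query]], function(s) {
    sum(joint$prob[joint[[query]] == s])
  }, numeric(1))
  structure(p / mass, variable = query, class = "stressbn_posterior")
}

#' Posterior probability of a designated target state
#'
#' Convenience wrapper around [variable_elimination()] for classification:
#' observed fields of a partial record become evidence; unobserved fields
#' are left unobserved; the probability of `target_state` is returned.
#'
#' @param bn a `stressbn_bn`.
#' @param target target variable name (must not be observed in `record`).
#' @param target_state the state whose probability is wanted.
#' @param record named list/vector of observed states (may be empty; `NA`
#'   entries are treated as unobserved and dropped).
#' @return probability in `[0, 1]`.
#' @export
predict_proba <- function(bn, target, target_state, record = list()) {
  record <- as.list(record)
  record <- record[!vapply(record, function(x) is.na(x) || x == "NR",
                           logical(1))]
  if (target %in% names(record)) {
    stop("target variable present in the record", call. = FALSE)
  }
  post <- variable_elimination(bn, target, record)
  if (!target_state %in% names(post)) {
    stop("unknown target state: ", target_state, call. = FALSE)
  }
  unname(post[[target_state]])
}

# Vectorized posterior of `target` when every other network variable is
# observed: only factors whose scope contains the target matter, so
# P(target = s | rest) is proportional to the product of those CPT entries.
# Equals variable_elimination row by row (tested), but O(nodes * n).
predict_proba_batch <- function(bn, target, target_state, data) {
  enc <- encode_data(data[, setdiff(bn$dag$nodes, target), drop = FALSE],
                     bn$variables[setdiff(bn$dag$nodes, target)])
  codes <- enc$codes
  n <- nrow(data)
  ts <- length(bn$variables[[target]])
  w <- matrix(1, nrow = n, ncol = ts)
  for (v in bn$dag$nodes) {
    cpt <- bn$cpts[[v]]
    fam <- c(v, cpt$parents)
    if (!target %in% fam) next
    sizes <- vapply(bn$variables[fam], length, integer(1))
    for (s in seq_len(ts)) {
      idx <- rep(0L, n)
      mult <- 1L
      for (k in seq_along(fam)) {
        fv <- fam[k]
        code <- if (fv == target) rep(s, n) else codes[, fv]
        idx <- idx + (code - 1L) * mult
        mult <- mult * sizes[k]
      }
      w[, s] <- w[, s] * as.vector(cpt$prob)[idx + 1L]
    }
  }
  tot <- rowSums(w)
  if (any(tot <= 0)) {
    stop_zero_evidence(list(record = which(tot <= 0)[1]))
  }
  si <- match(target_state, bn$variables[[target]])
  w[, si] / tot
}
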