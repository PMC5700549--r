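#' @title Discrete Bayesian network core
#' @description Data model for discrete Bayesian networks over named
#'   categorical variables: DAGs, conditional probability tables (CPTs),
#'   joint factorization p(x1..xn) = prod_i p(xi | parents(xi)), decomposable
#'   BIC/BDeu scoring, and greedy hill-climbing structure search.
#' @name bn_core
NULL

as_edge_matrix <- function(edges) {
  if (is.null(edges) || (is.matrix(edges) && nrow(edges) == 0) ||
      length(edges) == 0) {
    return(matrix(character(0), ncol = 2,
                  dimnames = list(NULL, c("from", "to"))))
  }
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (!is.matrix(edges)) edges <- matrix(edges, ncol = 2, byrow = TRUE)
  storage.mode(edges) <- "character"
  colnames(edges) <- c("from", "to")
  edges
}

#' Test whether a directed edge set is acyclic
#'
#' @param edges two-column character matrix or data frame of (from, to)
#'   pairs; a zero-row edge set is acyclic.
#' @param nodes optional character vector of node names (isolated nodes
#'   allowed); defaults to the nodes appearing in `edges`.
#' @return `TRUE` iff a topological order exists.
#' @export
#' @examples
#' check_acyclic(rbind(c("A", "B"), c("B", "C")))
#' check_acyclic(rbind(c("A", "B"), c("B", "A")))
check_acyclic <- function(edges, nodes = NULL) {
  edges <- as_edge_matrix(edges)
  if (is.null(nodes)) nodes <- unique(c(edges[, 1], edges[, 2]))
  if (any(edges[, 1] == edges[, 2])) return(FALSE)
  !is.null(topological_order(nodes, edges))
}

# Kahn's algorithm; NULL when a cycle exists.
topological_order <- function(nodes, edges) {
  edges <- as_edge_matrix(edges)
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  tb <- table(edges[, 2])
  indeg[names(tb)] <- as.integer(tb)
  out <- character(0)
  avail <- names(indeg)[indeg == 0]
  while (length(avail)) {
    v <- avail[1]
    avail <- avail[-1]
    out <- c(out, v)
    ch <- edges[edges[, 1] == v, 2]
    for (c in ch) {
      indeg[c] <- indeg[c] - 1L
      if (indeg[c] == 0L) avail <- c(avail, c)
    }
  }
  if (length(out) == length(nodes)) out else NULL
}

#' Construct a DAG over named variables
#'
#' @param nodes character vector of node names.
#' @param edges two-column (from, to) matrix/data frame, or `NULL`.
#' @return object of class `stressbn_dag` with fields `nodes` and `parents`
#'   (named list of parent-name vectors).
#' @export
new_dag <- function(nodes, edges = NULL) {
  stopifnot(is.character(nodes), !anyDuplicated(nodes))
  edges <- as_edge_matrix(edges)
  if (nrow(edges)) {
    unknown <- setdiff(c(edges[, 1], edges[, 2]), nodes)
    if (length(unknown)) stop("edge endpoint(s) not in nodes: ",
                              paste(unknown, collapse = ", "), call. = FALSE)
    if (anyDuplicated(paste(edges[, 1], edges[, 2]))) {
      stop("duplicate edges", call. = FALSE)
    }
  }
  if (!check_acyclic(edges, nodes)) stop("edges contain a directed cycle",
                                         call. = FALSE)
  parents <- lapply(stats::setNames(nodes, nodes),
                    function(v) unname(edges[edges[, 2] == v, 1]))
  structure(list(nodes = nodes, parents = parents), class = "stressbn_dag")
}

#' Edge matrix of a DAG
#' @param dag a `stressbn_dag`.
#' @return two-column character matrix (from, to).
#' @export
dag_edges <- function(dag) {
  e <- do.call(rbind, lapply(dag$nodes, function(v) {
    if (length(dag$parents[[v]])) cbind(from = dag$parents[[v]], to = v)
  }))
  as_edge_matrix(e)
}

#' @export
print.stressbn_dag <- function(x, ...) {
  cat("DAG with", length(x$nodes), "nodes and", nrow(dag_edges(x)),
      "edges\n")
  e <- dag_edges(x)
  if (nrow(e)) cat(paste(" ", e[, 1], "->", e[, 2], collapse = "\n"), "\n")
  invisible(x)
}

# ---- conditional probability tables ------------------------------------

# CPT array layout: dim = (child states, parent1 states, parent2 states, ...),
# dimnames named by variable; child dimension first.
new_cpt <- function(child, parents, prob) {
  structure(list(child = child, parents = parents, prob = prob),
            class = "stressbn_cpt")
}

cpt_check <- function(cpt, tol = 1e-12) {
  p <- cpt$prob
  if (any(p < -tol | p > 1 + tol)) return(FALSE)
  d <- dim(p)
  m <- matrix(p, nrow = d[1])
  all(abs(colSums(m) - 1) <= tol)
}

#' Construct a Bayesian network from a DAG and CPTs
#'
#' @param dag a [new_dag()] object.
#' @param variables named list of state-label vectors, one per node.
#' @param cpts named list of CPT arrays: for node `v` with parents
#'   `p1, p2, ...` an array with `dim = c(|v|, |p1|, |p2|, ...)` (child
#'   dimension first, parents in DAG parent order) whose child-state slices
#'   sum to 1 for every parent configuration. Root nodes take a probability
#'   vector.
#' @return object of class `stressbn_bn`.
#' @export
new_bn <- function(dag, variables, cpts) {
  stopifnot(inherits(dag, "stressbn_dag"))
  if (!setequal(names(variables), dag$nodes)) {
    stop("variables must name every DAG node", call. = FALSE)
  }
  bn_cpts <- list()
  for (v in dag$nodes) {
    pa <- dag$parents[[v]]
    p <- cpts[[v]]
    if (is.null(p)) stop("missing CPT for node ", v, call. = FALSE)
    dims <- c(length(variables[[v]]), vapply(variables[pa], length, integer(1)))
    p <- array(as.numeric(p), dim = dims,
               dimnames = c(list(variables[[v]]), variables[pa]))
    names(dimnames(p)) <- c(v, pa)
    cpt <- new_cpt(v, pa, p)
    if (!cpt_check(cpt)) {
      stop("CPT for node ", v,
           " is not normalized (child-state slices must sum to 1)",
           call. = FALSE)
    }
    bn_cpts[[v]] <- cpt
  }
  structure(list(dag = dag, variables = variables[dag$nodes], cpts = bn_cpts),
            class = "stressbn_bn")
}

#' @export
print.stressbn_bn <- function(x, ...) {
  cat("Discrete Bayesian network:", length(x$dag$nodes), "nodes,",
      nrow(dag_edges(x$dag)), "edges\n")
  for (v in x$dag$nodes) {
    pa <- x$dag$parents[[v]]
    cat(sprintf("  %s (%d states)%s\n", v, length(x$variables[[v]]),
                if (length(pa)) paste0(" | ", paste(pa, collapse = ", ")) else ""))
  }
  invisible(x)
}

#' Joint probability of a full assignment
#'
#' Evaluates the factorization `prod_i p(xi | parents(xi))` at one complete
#' state assignment.
#'
#' @param bn a `stressbn_bn`.
#' @param assignment named character vector/list: a state for every node.
#' @return probability in `[0, 1]`.
#' @export
joint_probability <- function(bn, assignment) {
  assignment <- unlist(assignment)
  if (!setequal(names(assignment), bn$dag$nodes)) {
    stop("assignment must cover every node", call. = FALSE)
  }
  prob <- 1
  for (v in bn$dag$nodes) {
    cpt <- bn$cpts[[v]]
    idx <- as.list(assignment[c(v, cpt$parents)])
    states_ok <- mapply(function(s, var) s %in% bn$variables[[var]],
                        idx, c(v, cpt$parents))
    if (!all(states_ok)) {
      stop("unknown state label in assignment for node ", v, call. = FALSE)
    }
    prob <- prob * do.call(`[`, c(list(cpt$prob), idx))
  }
  unname(prob)
}

# data frame of factors -> integer code matrix + state spaces
encode_data <- function(data, variables = NULL) {
  if (is.null(variables)) {
    variables <- lapply(data, function(x) {
      if (is.factor(x)) levels(x) else sort(unique(as.character(x)))
    })
  }
  codes <- lapply(names(variables), function(v) {
    x <- data[[v]]
    if (is.null(x)) stop("data lacks column ", v, call. = FALSE)
    i <- match(as.character(x), variables[[v]])
    if (anyNA(i) && !anyNA(x)) {
      stop("column ", v, " has states outside its declared space",
           call. = FALSE)
    }
    if (anyNA(i)) stop("column ", v, " has missing states; ",
                       "apply complete_cases_only() first", call. = FALSE)
    i
  })
  list(codes = do.call(cbind, stats::setNames(codes, names(variables))),
       variables = variables)
}

# counts array for one family: child states x parent configurations
family_counts <- function(codes, variables, child, parents) {
  sc <- length(variables[[child]])
  spa <- vapply(variables[parents], length, integer(1))
  ncfg <- prod(spa)
  idx <- codes[, child]
  if (length(parents)) {
    cfg <- integer(nrow(codes))
    mult <- 1L
    for (j in seq_along(parents)) {
      cfg <- cfg + (codes[, parents[j]] - 1L) * mult
      mult <- mult * spa[j]
    }
    idx <- idx + cfg * sc
  }
  matrix(tabulate(idx, nbins = sc * ncfg), nrow = sc)
}

#' Estimate CPTs for a given DAG from data
#'
#' Maximum-likelihood (pseudocount 0) or smoothed relative-frequency
#' estimation: each cell equals
#' `(count + pseudocount) / (config count + pseudocount * |child states|)`.
#' With pseudocount 0, parent configurations never seen in the data fall
#' back to a uniform child distribution.
#'
#' @param dag a [new_dag()] object.
#' @param data data frame of factors covering every DAG node, complete-case.
#' @param pseudocount nonnegative smoothing count per cell (default 0).
#' @param variables optional named list of state spaces; defaults to the
#'   factor levels of `data`.
#' @return a `stressbn_bn`.
#' @export
fit_parameters <- function(dag, data, pseudocount = 0, variables = NULL) {
  stopifnot(inherits(dag, "stressbn_dag"), pseudocount >= 0)
  if (nrow(data) == 0 && pseudocount == 0) {
    stop("empty data with pseudocount 0", call. = FALSE)
  }
  enc <- encode_data(data[, dag$nodes, drop = FALSE], variables)
  variables <- enc$variables
  cpts <- list()
  for (v in dag$nodes) {
    pa <- dag$parents[[v]]
    cnt <- family_counts(enc$codes, variables, v, pa)
    cnt <- cnt + pseudocount
    tot <- colSums(cnt)
    empty <- tot == 0
    if (any(empty)) cnt[, empty] <- 1  # unseen configuration -> uniform
    prob <- sweep(cnt, 2, colSums(cnt), "/")
    cpts[[v]] <- array(prob, dim = c(length(variables[[v]]),
                                     vapply(variables[pa], length, integer(1))))
  }
  new_bn(dag, variables, cpts)
}

# decomposable family scores ---------------------------------------------

family_loglik <- function(cnt) {
  tot <- colSums(cnt)
  nz <- cnt > 0
  sum(cnt[nz] * log(cnt[nz] / rep(tot, each = nrow(cnt))[nz]))
}

family_score <- function(codes, variables, child, parents, n,
                         score = "bic", ess = 1) {
  cnt <- family_counts(codes, variables, child, parents)
  sc <- nrow(cnt)
  ncfg <- ncol(cnt)
  if (score == "bic") {
    family_loglik(cnt) - log(n) / 2 * (sc - 1) * ncfg
  } else { # bdeu
    a_ij <- ess / ncfg
    a_ijk <- ess / (ncfg * sc)
    tot <- colSums(cnt)
    sum(lgamma(a_ij) - lgamma(a_ij + tot)) +
      sum(lgamma(a_ijk + cnt) - lgamma(a_ijk))
  }
}

#' Network score of a DAG given data
#'
#' Decomposable structure scores: `"bic"` (default) is the maximized
#' multinomial log-likelihood minus `log(N)/2` times the number of free
#' parameters; `"bdeu"` is the Bayesian-Dirichlet equivalent uniform
#' marginal likelihood with equivalent sample size `ess`. Both are sums of
#' per-node family scores and are likelihood-equivalent across
#' Markov-equivalent DAGs.
#'
#' @param dag a [new_dag()] object.
#' @param data complete-case data frame of factors.
#' @param score `"bic"` or `"bdeu"`.
#' @param ess equivalent sample size for BDeu.
#' @param variables optional state spaces (default: factor levels).
#' @return the log-score (unitless).
#' @export
bic_score <- function(dag, data, score = c("bic", "bdeu"), ess = 1,
                      variables = NULL) {
  score <- match.arg(score)
  enc <- encode_data(data[, dag$nodes, drop = FALSE], variables)
  sum(vapply(dag$nodes, function(v) {
    family_score(enc$codes, enc$variables, v, dag$parents[[v]],
                 nrow(data), score, ess)
  }, numeric(1)))
}

# ---- hill climbing ------------------------------------------------------

edge_key <- function(from, to) paste(from, to, sep = "\r")

has_path <- function(parents, from, to) {
  # TRUE if a directed path from `from` to `to` exists (children map search)
  stack <- from
  seen <- character(0)
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (v == to) return(TRUE)
    if (v %in% seen) next
    seen <- c(seen, v)
    ch <- names(parents)[vapply(parents, function(p) v %in% p, logical(1))]
    stack <- c(stack, ch)
  }
  FALSE
}

#' Greedy score-based structure search
#'
#' Hill climbing over single-edge moves (add, delete, reverse) under
#' acyclicity and optional edge constraints, maximizing a decomposable
#' score. Candidate moves are enumerated in a fixed order (move type add <
#' delete < reverse, then lexicographic by parent then child) and the first
#' of any tied best moves is taken, so a run is fully reproducible. With
#' `restarts > 0`, additional seeded searches start from random DAGs and the
#' best-scoring local optimum is returned.
#'
#' @param data complete-case data frame of factors (>= 2 columns).
#' @param score `"bic"` (default) or `"bdeu"`.
#' @param ess equivalent sample size for BDeu.
#' @param whitelist edges always present, two-column (from, to) matrix.
#' @param blacklist edges never present, same format. The preset
#'   [stress_sink_blacklist()] forbids all edges leaving the stress node.
#' @param restarts number of random restarts beyond the empty-graph start.
#' @param seed integer seed for the restarts (unused when `restarts = 0`).
#' @param max_parents cap on the in-degree of any node.
#' @param variables optional state spaces (default: factor levels).
#' @return the best local-optimum `stressbn_dag` found.
#' @export
hill_climb <- function(data, score = c("bic", "bdeu"), ess = 1,
                       whitelist = NULL, blacklist = NULL,
                       restarts = 0, seed = 1, max_parents = Inf,
                       variables = NULL) {
  score <- match.arg(score)
  if (ncol(data) < 2) stop("need at least 2 variables", call. = FALSE)
  enc <- encode_data(data, variables)
  variables <- enc$variables
  nodes <- names(variables)
  n <- nrow(data)
  whitelist <- as_edge_matrix(whitelist)
  blacklist <- as_edge_matrix(blacklist)
  if (nrow(whitelist) && nrow(blacklist)) {
    clash <- intersect(edge_key(whitelist[, 1], whitelist[, 2]),
                       edge_key(blacklist[, 1], blacklist[, 2]))
    if (length(clash)) stop("edge(s) both required and forbidden",
                            call. = FALSE)
  }
  if (nrow(whitelist) && !check_acyclic(whitelist, nodes)) {
    stop("whitelist edges are cyclic", call. = FALSE)
  }
  forbidden <- edge_key(blacklist[, 1], blacklist[, 2])
  required <- edge_key(whitelist[, 1], whitelist[, 2])

  cache <- new.env(parent = emptyenv())
  fam <- function(child, parents) {
    key <- paste(child, paste(sort(parents), collapse = ","), sep = "|")
    val <- cache[[key]]
    if (is.null(val)) {
      val <- family_score(enc$codes, variables, child, parents, n, score, ess)
      cache[[key]] <- val
    }
    val
  }

  ordered_pairs <- expand.grid(from = nodes, to = nodes,
                               stringsAsFactors = FALSE)
  ordered_pairs <- ordered_pairs[ordered_pairs$from != ordered_pairs$to, ]
  ordered_pairs <- ordered_pairs[order(ordered_pairs$from, ordered_pairs$to), ]

  climb <- function(parents) {
    scores <- vapply(nodes, function(v) fam(v, parents[[v]]), numeric(1))
    repeat {
      best_delta <- 1e-9
      best_apply <- NULL
      for (type in c("add", "delete", "reverse")) {
        for (r in seq_len(nrow(ordered_pairs))) {
          a <- ordered_pairs$from[r]
          b <- ordered_pairs$to[r]
          key <- edge_key(a, b)
          present <- a %in% parents[[b]]
          if (type == "add") {
            if (present || key %in% forbidden) next
            if (length(parents[[b]]) >= max_parents) next
            if (has_path(parents, b, a)) next
            delta <- fam(b, c(parents[[b]], a)) - scores[[b]]
            if (delta > best_delta) {
              best_delta <- delta
              best_apply <- list(type = "add", a = a, b = b)
            }
          } else if (type == "delete") {
            if (!present || key %in% required) next
            delta <- fam(b, setdiff(parents[[b]], a)) - scores[[b]]
            if (delta > best_delta) {
              best_delta <- delta
              best_apply <- list(type = "delete", a = a, b = b)
            }
          } else {
            if (!present || key %in% required) next
            if (edge_key(b, a) %in% forbidden) next
            if (length(parents[[a]]) >= max_parents) next
            p2 <- parents
            p2[[b]] <- setdiff(p2[[b]], a)
            if (has_path(p2, a, b)) next
            delta <- (fam(b, p2[[b]]) - scores[[b]]) +
              (fam(a, c(parents[[a]], b)) - scores[[a]])
            if (delta > best_delta) {
              best_delta <- delta
              best_apply <- list(type = "reverse", a = a, b = b)
            }
          }
        }
      }
      if (is.null(best_apply)) break
      a <- best_apply$a
      b <- best_apply$b
      if (best_apply$type == "add") {
        parents[[b]] <- c(parents[[b]], a)
      } else if (best_apply$type == "delete") {
        parents[[b]] <- setdiff(parents[[b]], a)
      } else {
        parents[[b]] <- setdiff(parents[[b]], a)
        parents[[a]] <- c(parents[[a]], b)
      }
      scores <- vapply(nodes, function(v) fam(v, parents[[v]]), numeric(1))
    }
    list(parents = parents, score = sum(scores))
  }

  start_parents <- lapply(stats::setNames(nodes, nodes), function(v) {
    unname(whitelist[whitelist[, 2] == v, 1])
  })
  best <- climb(start_parents)
  if (restarts > 0) {
    for (r in seq_len(restarts)) {
      parents <- with_seed(seed + r, random_start(nodes, start_parents,
                                                  forbidden, max_parents))
      res <- climb(parents)
      if (res$score > best$score + 1e-9) best <- res
    }
  }
  edges <- do.call(rbind, lapply(nodes, function(v) {
    if (length(best$parents[[v]])) cbind(from = best$parents[[v]], to = v)
  }))
  dag <- new_dag(nodes, edges)
  attr(dag, "score") <- best$score
  dag
}

# random acyclic start for restarts: try each candidate edge in random
# order, keep with probability 1/2 when legal
random_start <- function(nodes, start_parents, forbidden, max_parents) {
  parents <- start_parents
  cand <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  cand <- cand[cand$from != cand$to, ]
  cand <- cand[sample.int(nrow(cand)), ]
  for (r in seq_len(nrow(cand))) {
    a <- cand$from[r]
    b <- cand$to[r]
    if (stats::runif(1) > 0.5) next
    if (edge_key(a, b) %in% forbidden) next
    if (a %in% parents[[b]] || length(parents[[b]]) >= max_parents) next
    if (has_path(parents, b, a)) next
    parents[[b]] <- c(parents[[b]], a)
  }
  parents
}

#' Blacklist forbidding all edges out of a sink node
#'
#' Constraint preset reflecting the use of stress as the analysis target:
#' stress may receive edges but emit none.
#'
#' @param nodes all node names.
#' @param sink the sink node (default `"stress"`).
#' @return two-column (from, to) matrix suitable for `blacklist`.
#' @export
stress_sink_blacklist <- function(nodes, sink = "stress") {
  as_edge_matrix(cbind(from = sink, to = setdiff(nodes, sink)))
}

#' Export a DAG as Graphviz DOT text
#'
#' @param dag a `stressbn_dag`.
#' @return a single string: a `digraph` with one node declaration per node
#'   and one `a -> b;` line per edge.
#' @export
export_dot <- function(dag) {
  quote_id <- function(x) paste0("\"", gsub("\"", "\\\\\"", x), "\"")
  lines <- c("digraph bn {",
             paste0("  ", quote_id(dag$nodes), ";"),
             {
               e <- dag_edges(dag)
               if (nrow(e)) paste0("  ", quote_id(e[, 1]), " -> ",
                                   quote_id(e[, 2]), ";") else character(0)
             },
             "}")
  paste(lines, collapse = "\n")
}

# ---- JSON serialization -------------------------------------------------

# Parent configurations are serialized row-major in parent list order: the
# first parent varies slowest, the last fastest; each row holds the child
# state probabilities in declared order.
parent_config_grid <- function(sizes) {
  if (!length(sizes)) return(matrix(integer(0), nrow = 1, ncol = 0))
  as.matrix(rev(expand.grid(rev(lapply(sizes, seq_len)))))
}

#' Serialize a Bayesian network to JSON
#'
#' The layout records the variables with their state lists, the edge list,
#' and one CPT block per node whose `table` holds one row per parent
#' configuration (row-major in parent list order, parent states in declared
#' order; first parent slowest) and child-state probabilities in declared
#' order within each row.
#'
#' @param bn a `stressbn_bn`.
#' @param path optional file path; when given the JSON is written there.
#' @return the JSON string, invisibly when `path` is given.
#' @export
bn_to_json <- function(bn, path = NULL) {
  obj <- list(
    variables = lapply(bn$dag$nodes, function(v) {
      list(name = v, states = bn$variables[[v]])
    }),
    edges = apply(dag_edges(bn$dag), 1,
                  function(e) list(from = unname(e[1]), to = unname(e[2]))),
    cpts = lapply(stats::setNames(bn$dag$nodes, bn$dag$nodes), function(v) {
      cpt <- bn$cpts[[v]]
      sizes <- vapply(bn$variables[cpt$parents], length, integer(1))
      grid <- parent_config_grid(sizes)
      m <- matrix(cpt$prob, nrow = dim(cpt$prob)[1])
      # column index of config row i in the column-major array: first parent
      # fastest there, so convert explicitly
      col_idx <- apply(grid, 1, function(cfg) {
        j <- 0L
        mult <- 1L
        for (k in seq_along(cfg)) {
          j <- j + (cfg[k] - 1L) * mult
          mult <- mult * sizes[k]
        }
        j + 1L
      })
      if (!length(col_idx)) col_idx <- 1L
      list(parents = I(cpt$parents),
           table = lapply(col_idx, function(j) m[, j]))
    })
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Deserialize a Bayesian network from JSON
#'
#' @param x JSON string or file path produced by [bn_to_json()].
#' @return a `stressbn_bn`.
#' @export
bn_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  variables <- stats::setNames(
    lapply(obj$variables, function(v) unlist(v$states)),
    vapply(obj$variables, function(v) v$name, character(1)))
  edges <- if (length(obj$edges)) {
    do.call(rbind, lapply(obj$edges, function(e) c(e$from, e$to)))
  }
  dag <- new_dag(names(variables), edges)
  cpts <- lapply(stats::setNames(names(variables), names(variables)),
                 function(v) {
    blk <- obj$cpts[[v]]
    pa <- unlist(blk$parents)
    if (is.null(pa)) pa <- character(0)
    sizes <- vapply(variables[pa], length, integer(1))
    grid <- parent_config_grid(sizes)
    sc <- length(variables[[v]])
    m <- matrix(0, nrow = sc, ncol = max(1L, prod(sizes)))
    for (i in seq_len(nrow(grid))) {
      cfg <- grid[i, ]
      j <- 0L
      mult <- 1L
      for (k in seq_along(cfg)) {
        j <- j + (cfg[k] - 1L) * mult
        mult <- mult * sizes[k]
      }
      m[, j + 1L] <- unlist(blk$table[[i]])
    }
    array(m, dim = c(sc, sizes))
  })
  new_bn(dag, variables, cpts)
}

# evaluate-with-seed helper: runs code under a temporary RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
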