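# Fixture builders shared across the suite. All randomized fixtures take an
# explicit seed so every test is reproducible.

# Two-node chain A -> B over binary states, hand-set CPTs.
chain_bn <- function(p_a = 0.5, p_b_given_a1 = 0.8, p_b_given_a0 = 0.1) {
  new_bn(new_dag(c("A", "B"), rbind(c("A", "B"))),
         list(A = c("a1", "a0"), B = c("b1", "b0")),
         list(A = c(p_a, 1 - p_a),
              B = matrix(c(p_b_given_a1, 1 - p_b_given_a1,
                           p_b_given_a0, 1 - p_b_given_a0), nrow = 2)))
}

# Random discrete network: random DAG (edge prob 0.4 over an ordered node
# set), random state-space sizes in 2..max_states, Dirichlet-ish CPTs.
random_bn <- function(n_nodes, max_states = 3, seed = 1) {
  set.seed(seed)
  nodes <- LETTERS[seq_len(n_nodes)]
  sizes <- sample(2:max_states, n_nodes, replace = TRUE)
  variables <- lapply(seq_len(n_nodes), function(i) {
    paste0(tolower(nodes[i]), seq_len(sizes[i]))
  })
  names(variables) <- nodes
  edges <- NULL
  for (i in seq_len(n_nodes)) {
    for (j in seq_len(n_nodes)) {
      if (i < j && stats::runif(1) < 0.4) {
        edges <- rbind(edges, c(nodes[i], nodes[j]))
      }
    }
  }
  dag <- new_dag(nodes, edges)
  cpts <- lapply(nodes, function(v) {
    pa <- dag$parents[[v]]
    ncfg <- prod(vapply(variables[pa], length, integer(1)))
    sc <- length(variables[[v]])
    m <- matrix(stats::rgamma(sc * max(1, ncfg), shape = 1) + 0.05,
                nrow = sc)
    array(sweep(m, 2, colSums(m), "/"),
          dim = c(sc, vapply(variables[pa], length, integer(1))))
  })
  names(cpts) <- nodes
  new_bn(dag, variables, cpts)
}

# Random evidence over a subset of non-query nodes, drawn from observed
# states so the evidence has positive probability under the joint.
random_evidence <- function(bn, query, max_vars = 3) {
  cand <- setdiff(bn$dag$nodes, query)
  k <- sample(0:min(max_vars, length(cand)), 1)
  if (k == 0) return(list())
  vars <- sample(cand, k)
  ev <- lapply(vars, function(v) sample(bn$variables[[v]], 1))
  names(ev) <- vars
  ev
}

# All DAGs over the given nodes (exhaustive, for oracle scoring): every
# subset of ordered pairs that is acyclic and has no 2-cycle.
all_dags <- function(nodes) {
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  m <- nrow(pairs)
  out <- list()
  for (mask in 0:(2^m - 1)) {
    sel <- as.logical(bitwAnd(mask, 2^(seq_len(m) - 1)))
    e <- as.matrix(pairs[sel, , drop = FALSE])
    if (check_acyclic(e, nodes)) out[[length(out) + 1]] <- e
  }
  out
}

# A 10-node ground-truth network with bounded fan-in (chain plus a few
# extra parents), used for estimator-recovery checks where every family is
# well supported at moderate n.
bounded_fanin_bn <- function(seed = 5) {
  set.seed(seed)
  nodes <- paste0("V", 1:10)
  edges <- cbind(nodes[1:9], nodes[2:10])
  edges <- rbind(edges, c("V1", "V3"), c("V4", "V6"), c("V7", "V9"))
  variables <- stats::setNames(lapply(1:10, function(i) {
    paste0("s", seq_len(2 + i %% 2))
  }), nodes)
  dag <- new_dag(nodes, edges)
  cpts <- lapply(nodes, function(v) {
    pa <- dag$parents[[v]]
    sc <- length(variables[[v]])
    ncfg <- prod(vapply(variables[pa], length, integer(1)))
    m <- matrix(stats::rgamma(sc * max(1, ncfg), 2) + 0.3, nrow = sc)
    array(sweep(m, 2, colSums(m), "/"),
          dim = c(sc, vapply(variables[pa], length, integer(1))))
  })
  names(cpts) <- nodes
  new_bn(dag, variables, cpts)
}

# Independent brute-force Cronbach's alpha used as the formula oracle.
alpha_oracle <- function(m) {
  k <- ncol(m)
  k / (k - 1) * (1 - sum(apply(m, 2, var)) / var(rowSums(m)))
}
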