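test_that("acyclicity detection agrees with an independent graph library", {
  expect_true(check_acyclic(NULL))
  expect_true(check_acyclic(rbind(c("A", "B"), c("B", "C"))))
  expect_false(check_acyclic(rbind(c("A", "B"), c("B", "A"))))
  expect_false(check_acyclic(rbind(c("A", "A"))))
  library(igraph)
  set.seed(7)
  for (i in 1:40) {
    nodes <- LETTERS[1:5]
    pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$from != pairs$to, ]
    e <- as.matrix(pairs[runif(nrow(pairs)) < 0.25, , drop = FALSE])
    g <- make_empty_graph(n = 0, directed = TRUE) +
      vertices(nodes) + edges(as.vector(t(e)))
    expect_equal(check_acyclic(e, nodes), is_dag(g))
  }
})

test_that("the joint factorizes as the product of CPT entries and normalizes", {
  one <- new_bn(new_dag("A"), list(A = c("yes", "no")),
                list(A = c(0.3, 0.7)))
  expect_equal(joint_probability(one, c(A = "yes")), 0.3)
  bn <- chain_bn(p_a = 0.5, p_b_given_a1 = 0.8)
  expect_equal(joint_probability(bn, c(A = "a1", B = "b1")), 0.4)
  expect_error(joint_probability(bn, c(A = "a1", B = "nope")), "state")
  expect_error(joint_probability(bn, c(A = "a1")), "every node")
  for (seed in 1:5) {
    rbn <- random_bn(4, seed = seed)
    j <- enumerate_joint(rbn)
    expect_equal(sum(j$prob), 1, tolerance = 1e-10)
  }
})

test_that("parameter estimation matches count ratios, smoothing and fallbacks", {
  d1 <- data.frame(A = factor(c("yes", "yes", "yes", "no"),
                              levels = c("yes", "no")))
  bn1 <- fit_parameters(new_dag("A"), d1)
  expect_equal(as.vector(bn1$cpts$A$prob), c(0.75, 0.25))
  # smoothing-only uniform on empty data
  bn2 <- fit_parameters(new_dag("A"), d1[0, , drop = FALSE], pseudocount = 1,
                        variables = list(A = c("yes", "no")))
  expect_equal(as.vector(bn2$cpts$A$prob), c(0.5, 0.5))
  expect_error(fit_parameters(new_dag("A"), d1[0, , drop = FALSE]), "empty")
  # chain with all four combinations once: all conditionals one half
  d3 <- data.frame(A = factor(c("a1", "a1", "a0", "a0")),
                   B = factor(c("b1", "b0", "b1", "b0")))
  bn3 <- fit_parameters(new_dag(c("A", "B"), rbind(c("A", "B"))), d3)
  expect_equal(as.vector(bn3$cpts$B$prob), rep(0.5, 4))
  # unseen parent configuration -> uniform fallback at pseudocount 0
  d4 <- data.frame(A = factor(c("a1", "a1"), levels = c("a1", "a0")),
                   B = factor(c("b1", "b0"), levels = c("b1", "b0")))
  bn4 <- fit_parameters(new_dag(c("A", "B"), rbind(c("A", "B"))), d4)
  expect_equal(as.vector(bn4$cpts$B$prob[, 2]), c(0.5, 0.5))
  # all CPT rows normalized on random fits
  gt <- random_bn(5, seed = 3)
  d <- ancestral_sample(gt, 500, seed = 4)
  fit <- fit_parameters(gt$dag, d, pseudocount = 1, variables = gt$variables)
  for (v in fit$dag$nodes) {
    m <- matrix(fit$cpts[[v]]$prob, nrow = dim(fit$cpts[[v]]$prob)[1])
    expect_true(all(abs(colSums(m) - 1) < 1e-12))
  }
})

test_that("CPT estimates converge to the ground truth on a bounded-fan-in network", {
  gt <- bounded_fanin_bn()
  d <- ancestral_sample(gt, 100000, seed = 21)
  fit <- fit_parameters(gt$dag, d, variables = gt$variables)
  err <- max(vapply(gt$dag$nodes, function(v) {
    max(abs(fit$cpts[[v]]$prob - gt$cpts[[v]]$prob))
  }, numeric(1)))
  expect_lt(err, 0.02)
})

test_that("the BIC score is decomposable, likelihood-monotone and score-equivalent", {
  set.seed(11)
  d <- data.frame(A = factor(sample(c("a1", "a0"), 400, replace = TRUE)),
                  B = factor(sample(c("b1", "b0"), 400, replace = TRUE)),
                  C = factor(sample(c("c1", "c0"), 400, replace = TRUE)))
  empty <- new_dag(names(d))
  ab <- new_dag(names(d), rbind(c("A", "B")))
  # decomposability: adding an isolated variable's family score
  expect_equal(bic_score(ab, d),
               bic_score(new_dag(c("A", "B"), rbind(c("A", "B"))),
                         d[, c("A", "B")]) +
                 bic_score(new_dag("C"), d[, "C", drop = FALSE]))
  # score equivalence of Markov-equivalent one-edge structures
  ba <- new_dag(names(d), rbind(c("B", "A")))
  expect_equal(bic_score(ab, d), bic_score(ba, d), tolerance = 1e-9)
  expect_equal(bic_score(ab, d, score = "bdeu"),
               bic_score(ba, d, score = "bdeu"), tolerance = 1e-9)
  # the likelihood term never decreases when a parent is added
  loglik <- function(dag) bic_score(dag, d) +
    log(nrow(d)) / 2 * sum(vapply(dag$nodes, function(v) {
      prod(vapply(dag$parents[[v]], function(p) 2L, integer(1)))
    }, numeric(1)))
  expect_gte(loglik(ab) + 1e-9, loglik(empty))
  # independent variables at large n: empty graph beats any single edge
  set.seed(12)
  big <- data.frame(A = factor(sample(c("a1", "a0"), 5000, replace = TRUE)),
                    B = factor(sample(c("b1", "b0"), 5000, replace = TRUE)))
  e2 <- new_dag(c("A", "B"))
  expect_gte(bic_score(e2, big),
             bic_score(new_dag(c("A", "B"), rbind(c("A", "B"))), big))
})

test_that("hill climbing finds the exhaustive-score optimum and respects constraints", {
  # two independent fair coins: empty DAG
  set.seed(31)
  ind <- data.frame(A = factor(sample(c("a1", "a0"), 5000, replace = TRUE)),
                    B = factor(sample(c("b1", "b0"), 5000, replace = TRUE)))
  expect_equal(nrow(dag_edges(hill_climb(ind))), 0)
  # strong dependence: exactly one edge, either orientation
  set.seed(32)
  a <- sample(c("a1", "a0"), 5000, replace = TRUE)
  b <- ifelse(runif(5000) < 0.95, a, sample(c("a1", "a0"), 5000, TRUE))
  dep <- data.frame(A = factor(a), B = factor(sub("a", "b", b)))
  expect_equal(nrow(dag_edges(hill_climb(dep))), 1)
  # 3-node problems: local optimum equals the exhaustive-score maximum
  dags <- all_dags(c("A", "B", "C"))
  expect_length(dags, 25)
  for (seed in 1:6) {
    gt <- random_bn(3, max_states = 3, seed = seed + 50)
    d <- ancestral_sample(gt, 800, seed = seed)
    best_oracle <- max(vapply(dags, function(e) {
      bic_score(new_dag(c("A", "B", "C"), e), d)
    }, numeric(1)))
    found <- hill_climb(d, restarts = 3, seed = seed)
    expect_equal(attr(found, "score"), best_oracle, tolerance = 1e-9,
                 label = paste("seed", seed))
  }
  # constraints: whitelisted edges present, blacklisted absent, no cycles
  for (seed in 1:5) {
    gt <- random_bn(4, seed = seed + 70)
    d <- ancestral_sample(gt, 400, seed = seed)
    wl <- rbind(c("A", "B"))
    bl <- rbind(c("B", "C"), c("C", "A"))
    dag <- hill_climb(d, whitelist = wl, blacklist = bl, restarts = 2,
                      seed = seed)
    e <- dag_edges(dag)
    keys <- paste(e[, 1], e[, 2])
    expect_true("A B" %in% keys)
    expect_false(any(c("B C", "C A") %in% keys))
    expect_true(check_acyclic(e, dag$nodes))
  }
  expect_error(hill_climb(ind, whitelist = rbind(c("A", "B")),
                          blacklist = rbind(c("A", "B"))),
               "required and forbidden")
  # determinism: identical runs give identical graphs
  d <- ancestral_sample(random_bn(4, seed = 99), 300, seed = 1)
  g1 <- hill_climb(d, restarts = 2, seed = 5)
  g2 <- hill_climb(d, restarts = 2, seed = 5)
  expect_identical(dag_edges(g1), dag_edges(g2))
})

test_that("DOT export declares nodes and edges and can be parsed back", {
  empty <- new_dag(c("A", "B"))
  txt <- export_dot(empty)
  expect_match(txt, "digraph")
  expect_match(txt, "\"A\";")
  expect_false(grepl("->", txt))
  dag <- new_dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  txt <- export_dot(dag)
  expect_match(txt, "\"A\" -> \"B\";")
  # parse-back: recover the edge set from the emitted text
  lines <- strsplit(txt, "\n")[[1]]
  hits <- regmatches(lines, regexec("\"(\\w+)\" -> \"(\\w+)\";", lines))
  parsed <- do.call(rbind, lapply(hits[lengths(hits) == 3],
                                  function(h) h[2:3]))
  expect_setequal(paste(parsed[, 1], parsed[, 2]),
                  paste(dag_edges(dag)[, 1], dag_edges(dag)[, 2]))
})

test_that("JSON serialization round-trips networks without loss", {
  for (seed in c(2, 8)) {
    bn <- random_bn(4, max_states = 3, seed = seed)
    back <- bn_from_json(bn_to_json(bn))
    expect_identical(back$variables, bn$variables)
    expect_identical(dag_edges(back$dag), dag_edges(bn$dag))
    j1 <- enumerate_joint(bn)
    j2 <- enumerate_joint(back)
    expect_equal(j2$prob, j1$prob, tolerance = 1e-12)
  }
  # and through a file
  bn <- chain_bn()
  f <- tempfile(fileext = ".json")
  bn_to_json(bn, f)
  expect_equal(joint_probability(bn_from_json(f), c(A = "a1", B = "b1")),
               joint_probability(bn, c(A = "a1", B = "b1")))
})
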