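test_that("recArg1 effect set unions called genes and significant proteins
          with layer tags", {
  de <- de_table(c("a", "b", "x"), called = c(TRUE, TRUE, FALSE))
  pr <- prot_table(c("b", "c"), significant = c(TRUE, TRUE))
  hits <- recarg1_effect_set(de, pr)
  expect_setequal(hits$node, c("a", "b", "c"))
  expect_equal(sum(hits$node == "b"), 2)  # tagged in both layers
  expect_setequal(unique(hits$layer), c("transcriptome", "proteome"))

  none <- recarg1_effect_set(de_table("a", FALSE), prot_table("b", FALSE))
  expect_equal(nrow(none), 0)
})

test_that("arginine-dependent set obeys the exclusive-disjunction identity", {
  # direct truth-table evaluation over randomized call patterns
  set.seed(77)
  ids <- paste0("g", 1:40)
  for (rep in 1:50) {
    c1 <- sample(c(TRUE, FALSE), 40, replace = TRUE)  # M-CSF vs RANKL
    c2 <- sample(c(TRUE, FALSE), 40, replace = TRUE)  # rescue pair
    c3 <- sample(c(TRUE, FALSE), 40, replace = TRUE)  # starvation pair
    out <- arg_dependent_set(de_table(ids, c1), de_table(ids, c2),
                             de_table(ids, c3),
                             prot_table(character(0), logical(0)),
                             prot_table(character(0), logical(0)))
    expected <- ids[(c1 | c2) & !c3]
    expect_setequal(out$node[out$layer == "transcriptome"], expected)
  }
  # proteins: rescue-significant minus starvation-significant
  pids <- paste0("p", 1:10)
  s1 <- c(rep(TRUE, 6), rep(FALSE, 4))
  s2 <- rep(c(TRUE, FALSE), 5)
  out <- arg_dependent_set(de_table(character(0), logical(0)),
                           de_table(character(0), logical(0)),
                           de_table(character(0), logical(0)),
                           prot_table(pids, s1), prot_table(pids, s2))
  expect_setequal(out$node, pids[s1 & !s2])
  expect_error(arg_dependent_set(list(), de_table("a", TRUE),
                                 de_table("a", TRUE), prot_table("p", TRUE),
                                 prot_table("p", TRUE)),
               class = "missing_contrast")
})

test_that("prizes scale scores by beta and costs clamp 1 - weight", {
  net <- toy_network()
  hits <- data.frame(node = c("a", "b", "z"), score = c(2, 1, 5),
                     layer = "transcriptome", stringsAsFactors = FALSE)
  expect_message(pc <- build_prizes_costs(net, hits, beta = 2),
                 "1 hit\\(s\\) not in the network")
  expect_equal(unname(pc$prizes[c("a", "b", "c")]), c(4, 2, 0))
  expect_equal(pc$costs, pmin(pmax(1 - igraph::E(net)$weight, 1e-6), 1))
  expect_error(build_prizes_costs(net, hits, beta = 0),
               class = "invalid_beta")
  # a weight-1 edge keeps a strictly positive cost
  g1 <- igraph::make_graph(~ a - b)
  igraph::E(g1)$weight <- 1
  expect_equal(build_prizes_costs(g1, hits[0, ])$costs, 1e-6)
})

test_that("PCST heuristic solves the two-node toy exactly and always
          returns a tree", {
  g2 <- igraph::make_graph(~ a - b)
  igraph::E(g2)$weight <- 0.9
  pr <- c(a = 1, b = 1)
  sol <- pcst_heuristic(g2, pr, costs = 0.1, lambda = 1)
  expect_setequal(sol$nodes, c("a", "b"))
  expect_equal(sol$objective, 1.9)
  ex <- pcst_exact(g2, pr, costs = 0.1, lambda = 1)
  expect_equal(ex$objective, 1.9)

  # single prized node: singleton tree with its prize
  sol1 <- pcst_heuristic(toy_network(), c(d = 3),
                         costs = rep(0.5, igraph::ecount(toy_network())))
  expect_equal(sol1$nodes, "d")
  expect_equal(sol1$objective, 3)

  # all prizes zero: empty solution, objective 0
  expect_message(
    sol0 <- pcst_heuristic(toy_network(), c(a = 0),
                           costs = rep(0.5, 5)),
    "all prizes zero")
  expect_equal(sol0$objective, 0)

  # tree structure and monotone greedy trace on random instances
  set.seed(12)
  for (i in 1:10) {
    g <- gen_network(30, "scale_free", seed = 300 + i)
    hits <- data.frame(node = sample(igraph::V(g)$name, 6),
                       score = runif(6, 0.5, 2), layer = "t")
    pc <- build_prizes_costs(g, hits)
    sol <- pcst_heuristic(g, pc$prizes, pc$costs)
    expect_true(all(diff(sol$trace) >= -1e-12))
    if (length(sol$nodes) > 1) {
      sub <- igraph::graph_from_data_frame(sol$edges, directed = FALSE)
      expect_true(igraph::is_connected(sub))
      expect_equal(nrow(sol$edges), length(sol$nodes) - 1)
    }
  }
})

test_that("greedy PCST stays within 10% of the brute-force optimum on
          small graphs and matches it in most instances", {
  set.seed(5)
  eq <- 0L
  for (i in 1:50) {
    n <- sample(4:8, 1)
    repeat {
      g <- igraph::sample_gnp(n, 0.5)
      if (igraph::is_connected(g) && igraph::ecount(g) > 0) break
    }
    igraph::V(g)$name <- letters[seq_len(n)]
    igraph::E(g)$weight <- runif(igraph::ecount(g), 0.1, 1)
    nh <- sample(2:n, 1)
    hits <- data.frame(node = sample(letters[seq_len(n)], nh),
                       score = runif(nh, 0.2, 2), layer = "t")
    pc <- build_prizes_costs(g, hits)
    h <- pcst_heuristic(g, pc$prizes, pc$costs)
    ex <- pcst_exact(g, pc$prizes, pc$costs)
    expect_gte(h$objective, 0.9 * ex$objective)
    eq <- eq + (abs(h$objective - ex$objective) < 1e-9)
  }
  expect_gte(eq, 40)
})

test_that("tree overlap is plain set intersection", {
  expect_setequal(tree_overlap(list(nodes = c("a", "b", "c")),
                               list(nodes = c("b", "c", "d"))), c("b", "c"))
  expect_equal(length(tree_overlap(list(nodes = "a"), list(nodes = "b"))), 0)
  s <- list(nodes = c("x", "y"))
  expect_setequal(tree_overlap(s, s), c("x", "y"))
})

test_that("connected-subgraph sampler yields connected induced subgraphs
          of the requested size", {
  path <- igraph::make_graph(~ a - b, b - c, c - d)
  draws <- vapply(1:200, function(i) {
    paste(sort(sample_connected_subgraph(path, 2, seed = i)), collapse = "")
  }, character(1))
  expect_true(all(draws %in% c("ab", "bc", "cd")))

  g <- gen_network(120, "scale_free", seed = 3)
  for (i in 1:25) {
    s <- sample_connected_subgraph(g, 15, seed = i)
    expect_length(s, 15)
    expect_true(igraph::is_connected(igraph::induced_subgraph(g, s)))
  }
  expect_setequal(sample_connected_subgraph(path, 4, seed = 1),
                  c("a", "b", "c", "d"))
  expect_identical(sample_connected_subgraph(g, 10, seed = 9),
                   sample_connected_subgraph(g, 10, seed = 9))
  expect_error(sample_connected_subgraph(path, 5), class = "invalid_size")
})

test_that("overlap null matches the hypergeometric mean on complete graphs
          and flags real overlap on sparse ones", {
  k10 <- igraph::make_full_graph(10)
  igraph::V(k10)$name <- paste0("n", 1:10)
  on <- overlap_null(k10, 3, 3, observed_overlap = 0, n_draws = 2000,
                     seed = 4)
  # on K_n the sampler is uniform over subsets: mean overlap a*b/n = 0.9
  se <- sd(on$null_overlaps) / sqrt(on$n_draws)
  expect_lt(abs(mean(on$null_overlaps) - 0.9), 3 * se)
  expect_equal(on$p_empirical, 1)

  g <- gen_network(500, "scale_free", seed = 6)
  on2 <- overlap_null(g, 20, 20, observed_overlap = 20, n_draws = 500,
                      seed = 7)
  expect_lte(on2$p_empirical, 0.05)
  expect_error(overlap_null(k10, 3, 3, 5), class = "invalid_size")
  expect_error(overlap_null(k10, 3, 3, 0, n_draws = 0),
               class = "invalid_draws")
})
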