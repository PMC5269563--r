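test_that("CCF point estimates follow the diploid transform", {
  expect_equal(estimate_ccf(50, 100, 1), 1.0)
  expect_equal(estimate_ccf(20, 100, 0.8), 0.5)  # 2 * 0.2 / 0.8
  expect_equal(estimate_ccf(0, 100, 1), 0)
  expect_equal(estimate_ccf(90, 100, 1), 1)      # capped at 1
  expect_error(estimate_ccf(5, 0, 1), class = "neoepitree_validation_error")
  expect_error(estimate_ccf(5, 10, 0), class = "neoepitree_validation_error")
})

test_that("binomial mixture clustering recovers simple cluster structures", {
  set.seed(1)
  # one clone at VAF ~0.5
  tab1 <- make_tab(60, pos = 1:60, alt_count = rbinom(60, 200, 0.5),
                   depth = 200, consequence = "missense")
  cl1 <- cluster_mutations(tab1, seed = 2)
  expect_equal(cl1$K, 1)
  expect_lt(abs(cl1$clusters[[1]]$ccf - 1), 0.05)

  # two clones at VAF 0.5 and 0.1 -> CCFs 1.0 and 0.2
  tab2 <- make_tab(100, pos = 1:100,
                   alt_count = c(rbinom(50, 200, 0.5), rbinom(50, 200, 0.1)),
                   depth = 200, consequence = "missense")
  cl2 <- cluster_mutations(tab2, seed = 3)
  expect_equal(cl2$K, 2)
  ccfs <- sort(vapply(cl2$clusters, `[[`, numeric(1), "ccf"),
               decreasing = TRUE)
  expect_lt(abs(ccfs[1] - 1.0), 0.05)
  expect_lt(abs(ccfs[2] - 0.2), 0.05)

  expect_error(cluster_mutations(make_tab(0)),
               class = "neoepitree_validation_error")
})

test_that("tree search returns the unique feasible topology when forced", {
  # single cluster
  one <- make_clusters(1, n_per = 30, seed = 5)
  t1 <- fit_tree(one)
  expect_equal(t1$parent, c(C1 = "Normal"))

  # CCFs {1.0, 0.6, 0.5}: siblings are infeasible (0.6 + 0.5 > 1.0),
  # so the chain is the only surviving topology
  chain <- fit_tree(make_clusters(c(1.0, 0.6, 0.5), n_per = 60, seed = 6))
  expect_equal(chain$parent, c(C1 = "Normal", C2 = "C1", C3 = "C2"))
  expect_true(satisfies_sum_rule(chain, epsilon = 0.05))

  # infeasible configurations are an error, not a silent fallback.
  # A descending chain always satisfies the sum rule, so infeasibility
  # requires a cluster no parent (not even the root) can hold.
  bad <- make_clusters(c(0.5, 0.4), n_per = 30, seed = 7)
  bad$clusters[[1]]$ccf <- 1.3
  expect_error(fit_tree(bad, epsilon = 0.01),
               class = "neoepitree_validation_error")
})

test_that("selected trees equal the brute-force maximum for small cluster counts", {
  set.seed(8)
  for (i in 1:15) {
    K <- sample(2:4, 1)
    repeat {
      ccfs <- sort(round(runif(K, 0.15, 1), 2), decreasing = TRUE)
      if (K == 1 || min(-diff(ccfs)) > 0.08) break
    }
    clusters <- make_clusters(ccfs, n_per = 25, seed = 100 + i)
    tree <- tryCatch(fit_tree(clusters), error = function(e) NULL)
    pvs <- oracle_parent_vectors(K)
    scores <- apply(pvs, 1, oracle_tree_score, clusters = clusters)
    feasible <- !vapply(scores, is.null, TRUE)
    if (!any(feasible)) {
      expect_null(tree)
      next
    }
    best_score <- max(unlist(scores[feasible]))
    expect_false(is.null(tree))
    got_pv <- vapply(paste0("C", seq_len(K)), function(cl) {
      p <- tree$parent[[cl]]
      if (p == "Normal") 0L else as.integer(sub("C", "", p))
    }, 0L)
    got_score <- oracle_tree_score(got_pv, clusters)
    expect_equal(got_score, best_score, tolerance = 1e-9)
  }
})

test_that("chronology labels follow tree depth", {
  t1 <- make_single_clone_tree()
  expect_equal(unname(t1$label["C1"]), "ancestor")

  fork <- clone_tree(parent = c(C1 = "Normal", C2 = "Normal", C3 = "C1"),
                     ccf = c(Normal = 1, C1 = 0.6, C2 = 0.3, C3 = 0.4))
  expect_equal(unname(fork$label[c("C1", "C2", "C3")]),
               c("ancestor", "ancestor", "descendant"))

  chain <- clone_tree(parent = c(C1 = "Normal", C2 = "C1", C3 = "C2"),
                      ccf = c(Normal = 1, C1 = 1, C2 = 0.6, C3 = 0.3))
  expect_equal(unname(chain$label[c("C1", "C2", "C3")]),
               c("ancestor", "descendant", "later"))
})

test_that("fitted trees are invariant to mutation order", {
  tr <- simulate_clone_tree(3, 0.2, seed = 90)
  tab <- simulate_mutations(tr, 120, seed = 91)
  nonsyn <- tab[tab$consequence %in% c("missense", "nonsense"), ]
  f1 <- fit_clone_tree(nonsyn, seed = 92)
  shuffled <- nonsyn[rev(seq_len(nrow(nonsyn))), ]
  f2 <- fit_clone_tree(shuffled, seed = 92)
  expect_equal(f1$parent, f2$parent)
  expect_equal(f1$ccf, f2$ccf, tolerance = 1e-4)
})

test_that("recovery holds on a compact simulated sweep", {
  ok_K <- 0; ok_ml <- 0; n_unique <- 0; ok_unique <- 0; n <- 20
  for (i in 1:n) {
    K <- (i %% 3) + 1
    tr <- simulate_clone_tree(K, 0.2, seed = 200 + i)
    tab <- simulate_mutations(tr, 35 * K, seed = 300 + i)
    fit <- fit_clone_tree(tab, seed = 400 + i)
    expect_true(satisfies_sum_rule(fit, epsilon = 0.05))
    if (length(fit$nodes) == length(tr$nodes)) {
      ok_K <- ok_K + 1
      in_ml <- any(vapply(fit$ml_trees, identical, TRUE, tr$parent))
      if (in_ml) ok_ml <- ok_ml + 1
      if (length(fit$ml_trees) == 1) {
        n_unique <- n_unique + 1
        if (identical(fit$parent, tr$parent)) ok_unique <- ok_unique + 1
      }
    }
  }
  expect_gte(ok_K / n, 0.85)
  # the true topology sits in the maximum-likelihood set essentially always
  expect_gte(ok_ml / max(ok_K, 1), 0.9)
  # and whenever the maximum-likelihood tree is unique, it is the truth
  expect_gte(ok_unique / max(n_unique, 1), 0.9)
})
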