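make_assignments <- function(keys, genes, clones) {
  data.frame(key = keys, gene = genes, clone = clones,
             stringsAsFactors = FALSE)
}

make_calls <- function(keys, immunogenic, n_windows = 2) {
  data.frame(key = keys, immunogenic = immunogenic,
             n_windows = ifelse(immunogenic, n_windows, 0L),
             stringsAsFactors = FALSE)
}

test_that("epitope-tree annotation counts distinct genes and flags pathways", {
  tree <- make_single_clone_tree()
  a <- make_assignments(paste0("k", 1:4), c("GA", "GB", "GC", "GA"), "C1")
  calls <- make_calls(paste0("k", 1:4), c(TRUE, TRUE, FALSE, FALSE))
  et <- annotate_epitope_tree(tree, a, calls,
                              significant_pathways = list(PWX = c("GB", "GZ")))
  info <- et$clones$C1
  expect_equal(length(info$genes), 3)           # GA, GB, GC distinct
  expect_equal(info$epitope_genes, c("GA", "GB"))
  expect_equal(names(info$pathway_genes), "GB")
  expect_equal(info$pathway_genes$GB, "PWX")
  expect_equal(info$pathway_epitope_genes, "GB") # flagged gene with epitope
  expect_equal(unname(et$tier["C1"]), "trunk")

  # no immunogenic calls -> zero epitope counts everywhere
  et0 <- annotate_epitope_tree(tree, a, make_calls(paste0("k", 1:4),
                                                   rep(FALSE, 4)))
  expect_equal(length(et0$clones$C1$epitope_genes), 0)

  expect_error(annotate_epitope_tree(tree, make_assignments("k1", "G", "C9"),
                                     calls),
               class = "neoepitree_validation_error")
})

test_that("per-clone gene multisets conserve the per-tumor totals", {
  tree <- clone_tree(parent = c(C1 = "Normal", C2 = "C1", C3 = "C1"),
                     ccf = c(Normal = 1, C1 = 1, C2 = 0.5, C3 = 0.3))
  set.seed(21)
  n <- 40
  a <- make_assignments(paste0("k", 1:n),
                        sample(paste0("G", 1:12), n, TRUE),
                        sample(c("C1", "C2", "C3"), n, TRUE))
  calls <- make_calls(paste0("k", 1:n), runif(n) < 0.5)
  et <- annotate_epitope_tree(tree, a, calls)
  got <- sort(unlist(lapply(names(et$clones), function(cl)
    paste(cl, et$clones[[cl]]$genes))))
  want <- sort(unique(paste(a$clone, a$gene)))
  expect_equal(got, want)
  expect_equal(sum(vapply(et$clones, function(z) z$n_mutations, 0)), n)
  # epitope genes are a subset of mutated genes per clone
  for (cl in names(et$clones))
    expect_true(all(et$clones[[cl]]$epitope_genes %in% et$clones[[cl]]$genes))
})

test_that("target ranking is trunk-first, pathway-aware and order-invariant", {
  tree <- clone_tree(parent = c(C1 = "Normal", C2 = "C1", C3 = "C2"),
                     ccf = c(Normal = 1, C1 = 1, C2 = 0.6, C3 = 0.3))
  a <- make_assignments(c("k1", "k2", "k3", "k4"),
                        c("GA", "GB", "GC", "GD"),
                        c("C1", "C1", "C2", "C3"))
  calls <- make_calls(c("k1", "k2", "k3", "k4"), rep(TRUE, 4),
                      n_windows = c(1, 5, 9, 9))
  et <- annotate_epitope_tree(tree, a, calls,
                              significant_pathways = list(PW = "GA"))
  rk <- rank_targets(et)
  # trunk candidates first; within trunk the pathway member leads despite
  # fewer supporting windows
  expect_equal(rk$gene[1:2], c("GA", "GB"))
  expect_equal(rk$tier, c("trunk", "trunk", "major_branch", "leaf"))

  shuffled <- annotate_epitope_tree(tree, a[c(3, 1, 4, 2), ],
                                    calls[c(4, 2, 1, 3), ],
                                    significant_pathways = list(PW = "GA"))
  expect_equal(rank_targets(shuffled), rk)

  # removing trunk mutations removes exactly the trunk candidates
  keep <- a$clone != "C1"
  et2 <- annotate_epitope_tree(tree, a[keep, ], calls[keep, ],
                               significant_pathways = list(PW = "GA"))
  rk2 <- rank_targets(et2)
  expect_false(any(rk2$tier == "trunk"))
  expect_true(all(rk$gene[rk$tier == "leaf"] %in% rk2$gene))
})

test_that("major-branch tier requires the dominant descendant subtree", {
  tree <- clone_tree(parent = c(C1 = "Normal", C2 = "C1", C3 = "C1"),
                     ccf = c(Normal = 1, C1 = 1, C2 = 0.5, C3 = 0.3))
  a <- make_assignments(paste0("k", 1:10), paste0("G", 1:10),
                        c("C1", rep("C2", 7), rep("C3", 2)))
  calls <- make_calls(paste0("k", 1:10), rep(TRUE, 10))
  et <- annotate_epitope_tree(tree, a, calls)
  expect_equal(unname(et$tier[c("C1", "C2", "C3")]),
               c("trunk", "major_branch", "leaf"))
})

test_that("a three-mutation patient with no epitopes yields an all-zero epitope tree", {
  tree <- make_single_clone_tree()
  a <- make_assignments(paste0("k", 1:3), paste0("G", 1:3), "C1")
  calls <- make_calls(paste0("k", 1:3), rep(FALSE, 3))
  et <- annotate_epitope_tree(tree, a, calls)
  expect_equal(length(et$clones$C1$genes), 3)
  expect_equal(length(et$clones$C1$epitope_genes), 0)
  expect_equal(nrow(rank_targets(et)), 0)
})

test_that("the pipeline composes end to end on a small cohort", {
  cfg <- sim_config(n_tumors = 3, mutations_per_tumor_mean = 50,
                    n_pathways = 6, hpv_pairs_per_tumor = 20, seed = 77)
  out <- withr::local_tempdir()
  res <- run_pipeline(cfg, out, n_perm = 300, quiet = TRUE)

  expect_equal(length(res$patients), 3)
  for (sid in names(res$patients)) {
    p <- res$patients[[sid]]
    # filtering removed the injected panel contaminants
    injected <- res$cohort$truth$tumors[[sid]]$panel_injected
    expect_false(any(p$filtered$key %in% injected))
    # per-patient immunogenic counts equal the generator's truth
    expect_equal(sort(p$calls$key[p$calls$immunogenic]),
                 sort(unlist(res$cohort$truth$tumors[[sid]]$immunogenic_keys)))
    # epitope-tree conservation against the fitted assignment
    n_assigned <- sum(vapply(p$epitope_tree$clones,
                             function(z) z$n_mutations, 0))
    expect_equal(n_assigned, sum(p$filtered$consequence %in%
                                   c("missense", "nonsense")))
  }
  # outputs exist per manifest
  manifest <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_true(all(file.exists(file.path(out, unlist(manifest$files)))))
  # HPV truth: no false evidence, and chimeric pairs recovered
  for (sid in names(res$patients)) {
    truth_ids <- sort(unlist(res$cohort$truth$tumors[[sid]]$chimeric_pair_ids))
    got <- res$patients[[sid]]$integration$pair_id
    expect_true(all(got %in% truth_ids))
    expect_gte(length(got), ceiling(0.8 * length(truth_ids)))
  }
})
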