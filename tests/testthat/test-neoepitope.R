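test_that("peptide extraction windows the protein correctly at body and termini", {
  prot <- paste(rep(c("A", "R", "N", "D", "C"), 5), collapse = "") # length 25
  p <- extract_peptide_pair(prot, 9, substr(prot, 9, 9), "W")
  expect_equal(nchar(p$wild_type), 17)
  expect_equal(p$mutated_offset, 9)
  expect_equal(p$wild_type, substr(prot, 1, 17))
  expect_equal(substr(p$mutant, 9, 9), "W")
  expect_equal(sum(strsplit(p$mutant, "")[[1]] !=
                     strsplit(p$wild_type, "")[[1]]), 1)

  # N-terminal truncation
  p1 <- extract_peptide_pair(prot, 1, substr(prot, 1, 1), "W")
  expect_equal(nchar(p1$wild_type), 9)
  expect_equal(p1$mutated_offset, 1)

  # short protein: peptide is the whole protein
  short <- "MKTAYIAKQR"
  p2 <- extract_peptide_pair(short, 5, "Y", "F")
  expect_equal(p2$wild_type, short)
  expect_equal(p2$mutated_offset, 5)

  expect_error(extract_peptide_pair(prot, 9, "W", "A", protein_id = "px"),
               "px", class = "neoepitree_annotation_error")
  expect_error(extract_peptide_pair(prot, 9, "A", "A"),
               class = "neoepitree_validation_error")
})

test_that("window enumeration yields aligned windows containing the mutation", {
  prot <- paste(sample(c("A", "R", "N", "D"), 25, TRUE), collapse = "")
  pair <- extract_peptide_pair(prot, 9, substr(prot, 9, 9),
                               setdiff(c("A", "R", "N", "D", "W"),
                                       substr(prot, 9, 9))[1])
  win <- enumerate_windows(pair, 9)
  expect_equal(nrow(win), 9)
  expect_equal(win$window_start, 1:9)
  for (i in seq_len(nrow(win))) {
    expect_equal(nchar(win$mutant[i]), 9)
    # the mutated residue is inside every window: mutant differs from wt
    expect_false(win$mutant[i] == win$wild_type[i])
  }

  nine <- extract_peptide_pair("MKTAYIAKQ", 1, "M", "L")
  expect_equal(nrow(enumerate_windows(nine, 9)), 1)
  expect_equal(nrow(enumerate_windows(
    extract_peptide_pair("MKTAYIA", 3, "T", "S"), 9)), 0)
  expect_error(enumerate_windows(nine, 12),
               class = "neoepitree_validation_error")
})

test_that("the 50/500 rule fires only when a shared-start window qualifies", {
  pair <- extract_peptide_pair("MKTAYIAKQLLRWSNPQ", 9, "Q", "H")
  # stub predictor keyed on exact peptides: one qualifying window
  win <- enumerate_windows(pair, 9)
  lut <- c(stats::setNames(rep(600, nrow(win)), win$wild_type),
           stats::setNames(rep(200, nrow(win)), win$mutant))
  lut[[win$mutant[3]]] <- 30
  pred <- function(pep, allele) unname(lut[pep])
  call <- call_immunogenic(pair, "HLA-A0201", pred, key = "k1")
  expect_true(call$immunogenic)
  expect_equal(nrow(call$windows), 1)
  expect_equal(call$windows$window_start, win$window_start[3])
  expect_equal(call$windows$mutant_nM, 30)
  expect_equal(call$windows$wildtype_nM, 600)

  # wild-type binds everywhere -> never immunogenic even with mutant at 30
  pred_bind <- function(pep, allele)
    ifelse(pep %in% win$mutant, 30, 400)
  expect_false(call_immunogenic(pair, "HLA-A0201", pred_bind)$immunogenic)

  # predictor failure aborts the call
  pred_bad <- function(pep, allele) stop("backend down")
  expect_error(call_immunogenic(pair, "HLA-A0201", pred_bad),
               "backend down", class = "neoepitree_validation_error")
})

test_that("calls equal a brute-force re-scan of the window-by-allele grid", {
  tr <- simulate_clone_tree(1, seed = 50)
  tab <- simulate_mutations(tr, 120, seed = 51)
  pr <- simulate_proteome(tab, seed = 52)
  pred <- make_mock_predictor(0.55)
  mis <- pr$table[pr$table$consequence == "missense", ]
  for (i in seq_len(min(nrow(mis), 50))) {
    prot <- pr$proteome[[mis$gene[i]]]
    pair <- extract_peptide_pair(prot, mis$protein_pos[i], mis$aa_ref[i],
                                 mis$aa_alt[i])
    got <- call_immunogenic(pair, TEST_ALLELES, pred)$immunogenic
    # independent re-scan: raw substring loops and direct threshold checks
    expected <- FALSE
    L <- nchar(pair$wild_type)
    if (L >= 9) {
      for (s in 1:(L - 8)) {
        if (s > pair$mutated_offset || s + 8 < pair$mutated_offset) next
        mw <- substr(pair$mutant, s, s + 8)
        ww <- substr(pair$wild_type, s, s + 8)
        for (al in TEST_ALLELES)
          if (pred(mw, al) < 50 && pred(ww, al) > 500) expected <- TRUE
      }
    }
    expect_equal(got, expected, info = mis$key[i])
  }
})

test_that("immunogenic calls are monotone in the thresholds", {
  tr <- simulate_clone_tree(1, seed = 60)
  tab <- simulate_mutations(tr, 80, seed = 61)
  pr <- simulate_proteome(tab, seed = 62)
  pred <- make_mock_predictor(0.55)
  mis <- pr$table[pr$table$consequence == "missense", ]
  for (i in seq_len(min(nrow(mis), 30))) {
    pair <- extract_peptide_pair(pr$proteome[[mis$gene[i]]],
                                 mis$protein_pos[i], mis$aa_ref[i],
                                 mis$aa_alt[i])
    strict <- call_immunogenic(pair, TEST_ALLELES, pred, strong = 50,
                               weak = 500)$immunogenic
    relaxed <- call_immunogenic(pair, TEST_ALLELES, pred, strong = 80,
                                weak = 300)$immunogenic
    if (strict) expect_true(relaxed)
  }
})

test_that("cohort epitope counts respect class hierarchies and truth", {
  tr <- simulate_clone_tree(2, 0.2, seed = 70)
  tabs <- lapply(1:3, function(i)
    simulate_mutations(tr, 60, sample_id = paste0("S", i), seed = 70 + i))
  combined <- do.call(rbind, tabs)
  pr <- simulate_proteome(combined, seed = 74)
  pred <- make_mock_predictor(0.55)

  counts <- cohort_epitope_counts(pr$table, pr$proteome, TEST_ALLELES, pred)
  expect_equal(nrow(counts), 3)
  expect_true(all(counts$n_immunogenic <= counts$n_missense))
  expect_true(all(counts$n_missense <= counts$n_nonsynonymous))

  # a predictor that never binds yields all-zero immunogenic counts
  none <- cohort_epitope_counts(pr$table, pr$proteome, TEST_ALLELES,
                                function(pep, allele) rep(50000,
                                                          length(pep)))
  expect_true(all(none$n_immunogenic == 0))

  # unknown proteins are skipped and reported
  drop <- pr$proteome[-(1:2)]
  calls <- call_epitopes(pr$table, drop, TEST_ALLELES, pred)
  expect_gt(length(attr(calls, "skipped")), 0)
})

test_that("identical inputs give byte-identical call sets", {
  tr <- simulate_clone_tree(1, seed = 80)
  tab <- simulate_mutations(tr, 60, seed = 81)
  pr <- simulate_proteome(tab, seed = 82)
  pred <- make_mock_predictor(0.55)
  c1 <- call_epitopes(pr$table, pr$proteome, TEST_ALLELES, pred)
  c2 <- call_epitopes(pr$table, pr$proteome, TEST_ALLELES, pred)
  expect_identical(c1, c2)
})
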