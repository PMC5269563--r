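test_that("simulated clone trees satisfy the prevalence sum rule and separation", {
  tr1 <- simulate_clone_tree(1, seed = 1)
  expect_equal(tr1$parent, c(C1 = "Normal"))
  expect_equal(unname(tr1$ccf["C1"]), 1.0)

  for (i in 1:200) {
    n <- (i %% 3) + 1
    tr <- simulate_clone_tree(n, 0.15, seed = i)
    expect_true(satisfies_sum_rule(tr, epsilon = 0))
    ccfs <- tr$ccf[setdiff(tr$nodes, "Normal")]
    if (n > 1) expect_gte(min(abs(diff(sort(ccfs)))), 0.15)
  }
  expect_error(simulate_clone_tree(6, 0.3),
               class = "neoepitree_validation_error")
  expect_error(simulate_clone_tree(0), class = "neoepitree_validation_error")
})

test_that("simulated read counts track purity * CCF / 2 and are reproducible", {
  # clonal het, full purity: E[VAF] = 0.5
  tr <- make_single_clone_tree(1)
  tab <- simulate_mutations(tr, 300, depth_mean = 181, purity = 1, seed = 2)
  expect_lt(abs(mean(tab$alt_count / tab$depth) - 0.5), 0.02)

  # CCF 0.5 at purity 0.8: E[VAF] = 0.8 * 0.5 / 2 = 0.2
  tr2 <- make_single_clone_tree(0.5)
  tab2 <- simulate_mutations(tr2, 300, depth_mean = 181, purity = 0.8,
                             seed = 3)
  expect_lt(abs(mean(tab2$alt_count / tab2$depth) - 0.2), 0.02)

  expect_identical(simulate_mutations(tr, 50, seed = 9),
                   simulate_mutations(tr, 50, seed = 9))
  expect_error(simulate_mutations(simulate_clone_tree(3, 0.15, seed = 1), 2),
               class = "neoepitree_validation_error")
})

test_that("simulated proteomes match the annotations they rewrite", {
  tr <- simulate_clone_tree(2, 0.2, seed = 4)
  tab <- simulate_mutations(tr, 400, seed = 5)
  pr <- simulate_proteome(tab, flank = 8, seed = 6)
  snv <- pr$table[pr$table$consequence %in%
                    c("missense", "synonymous", "nonsense"), ]
  for (i in seq_len(nrow(snv)))
    expect_equal(substr(pr$proteome[[snv$gene[i]]], snv$protein_pos[i],
                        snv$protein_pos[i]), snv$aa_ref[i])
  # ~5% of SNVs deliberately land within a flank of a terminus
  lens <- nchar(pr$proteome[snv$gene])
  near <- snv$protein_pos <= 8 | snv$protein_pos > lens - 8
  expect_gt(mean(near), 0.01)
  expect_lt(mean(near), 0.12)
})

test_that("the mock affinity predictor is pure, validated, and calibrated", {
  p1 <- mock_affinity_predictor("MKTAYIAKQ", "HLA-A0201")
  p2 <- mock_affinity_predictor("MKTAYIAKQ", "HLA-A0201")
  expect_identical(p1, p2)
  expect_error(mock_affinity_predictor("MKTAYIAKX", "HLA-A0201"),
               class = "neoepitree_validation_error")
  expect_error(mock_affinity_predictor("MKTA", "HLA-A0201"),
               class = "neoepitree_validation_error")
  aff <- mock_affinity_predictor(
    vapply(1:500, function(i) {
      set.seed(i); paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G"),
                                9, TRUE), collapse = "")
    }, ""), "HLA-A0201")
  expect_true(all(aff >= 1 & aff <= 50000))
})

test_that("every truth-flagged immunogenic mutation has a qualifying window", {
  tr <- simulate_clone_tree(1, seed = 11)
  tab <- simulate_mutations(tr, 150, seed = 12)
  pr <- simulate_proteome(tab, seed = 13)
  pred <- make_mock_predictor(0.55)
  calls <- call_epitopes(pr$table, pr$proteome, TEST_ALLELES, pred)
  mis <- pr$table[pr$table$consequence == "missense", ]
  for (i in which(calls$immunogenic)) {
    row <- mis[mis$key == calls$key[i], ]
    pair <- extract_peptide_pair(pr$proteome[[row$gene]], row$protein_pos,
                                 row$aa_ref, row$aa_alt)
    cl <- call_immunogenic(pair, TEST_ALLELES, pred)
    expect_true(all(cl$windows$mutant_nM < 50))
    expect_true(all(cl$windows$wildtype_nM > 500))
  }
})

test_that("HPV read simulation controls chimera counts and recovers origins", {
  refs <- simulate_references(seed = 20)
  none <- simulate_hpv_reads(refs$host, refs$hpv, 50, 0, seed = 21)
  expect_equal(length(none$chimeric_ids), 0)
  expect_true(all(none$origins$origin1 == none$origins$origin2))

  some <- simulate_hpv_reads(refs$host, refs$hpv, 100, 5, seed = 22)
  expect_equal(length(some$chimeric_ids), 5)
  mixed <- some$origins$origin1 != some$origins$origin2
  expect_equal(sort(some$origins$pair_id[mixed]), some$chimeric_ids)
  expect_error(simulate_hpv_reads(refs$host, refs$hpv, 5, 6, seed = 1),
               class = "neoepitree_validation_error")

  # matcher recovers the true origin of noisy reads
  idx <- kmer_index(c(refs$host, refs$hpv))
  reads <- c(some$pairs$read1, some$pairs$read2)
  origins <- c(some$origins$origin1, some$origins$origin2)
  hits <- vapply(seq_along(reads), function(i)
    match_read(reads[i], idx)$reference == origins[i], TRUE)
  expect_gte(mean(hits), 0.99)
})

test_that("cohort simulation is reproducible and closes over the package readers", {
  cfg <- sim_config(n_tumors = 3, mutations_per_tumor_mean = 40,
                    n_pathways = 6, hpv_pairs_per_tumor = 20, seed = 33)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_cohort(cfg, d1)
  simulate_cohort(cfg, d2)
  files <- list.files(d1, recursive = TRUE)
  expect_identical(files, list.files(d2, recursive = TRUE))
  for (f in files)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  # every emitted file parses with the package's own readers
  expect_silent(read_fasta(file.path(d1, "proteome.fasta")))
  expect_silent(read_fasta(file.path(d1, "references.fasta")))
  expect_gt(length(read_gmt(file.path(d1, "pathways.gmt"))$pathways), 0)
  expect_s3_class(read_panel(file.path(d1, "panel.tsv")), "population_panel")
  for (sid in c("S1", "S2", "S3")) {
    expect_gt(nrow(read_mutation_table(
      file.path(d1, paste0(sid, ".mutations.tsv")), "tsv")), 0)
    expect_gt(nrow(read_mutation_table(
      file.path(d1, paste0(sid, ".mutations.vcf")), "vcf")), 0)
    expect_gt(length(read_fasta(file.path(d1, paste0(sid, ".reads.fasta")))),
              0)
  }
  truth <- jsonlite::read_json(file.path(d1, "truth.json"))
  expect_equal(length(truth$tumors), 3)
})
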