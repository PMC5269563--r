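test_that("population filtering partitions the input by panel MAF at the threshold", {
  tab <- make_tab(4, pos = c(10, 20, 30, 40))
  keys <- mutation_key(tab$chrom, tab$pos, tab$ref, tab$alt)
  panel <- population_panel(data.frame(
    chrom = "chr1", pos = c(10, 20, 30), ref = "A", alt = "G",
    maf = c(0.2, 0.05, 0.1)), "p")

  res <- filter_population_variants(tab, panel, maf_threshold = 0.1)
  # MAF 0.2 and MAF 0.10 (>= threshold) removed; MAF 0.05 and absent kept
  expect_equal(res$removed$pos, c(10, 30))
  expect_equal(res$kept$pos, c(20, 40))
  expect_equal(nrow(res$kept) + nrow(res$removed), nrow(tab))
  expect_equal(c(res$kept$key, res$removed$key)[order(c(res$kept$pos,
                                                        res$removed$pos))],
               keys)

  none <- filter_population_variants(tab, list(), maf_threshold = 0.1)
  expect_equal(nrow(none$kept), 4)
  expect_equal(nrow(none$removed), 0)
})

test_that("codon annotator matches exhaustive translation over all single-base changes", {
  bases <- c("A", "C", "G", "T")
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)
  n_checked <- 0
  for (codon in codons) {
    for (at in 1:3) {
      ref <- substr(codon, at, at)
      for (alt in setdiff(bases, ref)) {
        mutated <- codon
        substr(mutated, at, at) <- alt
        aa_ref <- code[[codon]]
        aa_alt <- code[[mutated]]
        expected <- if (aa_ref == aa_alt) "synonymous"
                    else if (aa_alt == "*") "nonsense"
                    else if (aa_ref == "*") "other"
                    else "missense"
        got <- classify_consequence(codon, at, ref, alt)
        expect_equal(got, expected,
                     info = sprintf("%s pos %d %s>%s", codon, at, ref, alt))
        n_checked <- n_checked + 1
      }
    }
  }
  expect_equal(n_checked, 576)
})

test_that("codon annotator handles frames, indels and reference mismatches", {
  cds <- "ATGGCTTGGTAA"  # M A W *
  expect_equal(classify_consequence(cds, 6, "T", "C"), "synonymous") # GCT>GCC
  expect_equal(classify_consequence(cds, 9, "G", "A"), "nonsense")   # TGG>TGA
  expect_equal(classify_consequence(cds, 5, "C", "T"), "missense")   # GCT>GTT
  expect_equal(classify_consequence(cds, 3, "GGC", "G"), "deletion")
  expect_equal(classify_consequence(cds, 3, "G", "GAA"), "insertion")
  expect_error(classify_consequence(cds, 6, "A", "C"),
               class = "neoepitree_validation_error")
})

test_that("substitution spectrum covers the 12 directed classes and normalises", {
  one <- make_tab(1, ref = "C", alt = "T",
                  consequence = "missense")
  sp <- substitution_spectrum(one)
  expect_equal(unname(sp$frequency[["C>T"]]), 1.0)
  expect_equal(sum(sp$frequency), 1.0)

  set.seed(41)
  bases <- c("A", "C", "G", "T")
  n <- 10000
  ref <- sample(bases, n, TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  tab <- make_tab(n, pos = seq_len(n), ref = ref, alt = alt,
                  gene = "G1", consequence = "missense")
  sp2 <- substitution_spectrum(tab)
  expect_equal(sum(sp2$frequency), 1)
  # uniform simulation: every class within a generous multinomial CI of 1/12
  expect_true(all(abs(sp2$frequency - 1 / 12) < 4 * sqrt((1 / 12) * (11 / 12) / n)))

  # indels are skipped with a count
  mixed <- rbind(make_tab(2, pos = 1:2, ref = "C", alt = "T",
                          consequence = "missense"),
                 make_tab(1, pos = 3, ref = "CA", alt = "C",
                          consequence = "deletion"))
  sp3 <- substitution_spectrum(mixed)
  expect_equal(sp3$n_skipped, 1)
})

test_that("gene recurrence counts each patient once and prints half-up percents", {
  tabs <- lapply(1:23, function(i)
    make_tab(2, sample_id = paste0("S", i), pos = c(i * 10, i * 10 + 1),
             gene = if (i <= 4) c("PIK3CA", "PIK3CA") else c("OTHER1", "OTHER2")))
  rec <- gene_recurrence(tabs, n_patients = 23)
  # four of 23 patients -> 17.4%, multiplicity within a patient ignored
  expect_equal(rec$n_patients[rec$gene == "PIK3CA"], 4L)
  expect_equal(rec$percent[rec$gene == "PIK3CA"], 17.4)
  expect_false("ABSENT" %in% rec$gene)

  shuffled <- do.call(rbind, tabs)
  shuffled <- shuffled[sample(nrow(shuffled)), ]
  expect_equal(gene_recurrence(shuffled, n_patients = 23), rec)

  # duplicating every patient under new ids doubles counts, keeps percents
  dup <- c(tabs, lapply(tabs, function(t) {
    t$sample_id <- paste0(t$sample_id, "bis"); t
  }))
  rec2 <- gene_recurrence(dup, n_patients = 46)
  expect_equal(rec2$n_patients[rec2$gene == "PIK3CA"], 8L)
  expect_equal(rec2$percent[rec2$gene == "PIK3CA"], 17.4)
})

test_that("cohort summary conserves totals by consequence class", {
  empty <- cohort_summary(make_tab(0))
  expect_equal(empty$total, 0)
  expect_true(all(empty$by_class == 0))

  set.seed(43)
  tr <- make_single_clone_tree()
  tab <- simulate_mutations(tr, 500, seed = 44)
  cs <- cohort_summary(tab)
  expect_equal(cs$total, 500)
  expect_equal(sum(cs$by_class), 500)
  expect_equal(unname(cs$per_patient[["S1"]]), 500)
})
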