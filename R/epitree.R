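# The per-patient "cancer neo-epitope tree": the clone tree annotated with
# per-clone mutated-gene counts, neo-epitope-bearing genes and significant-
# pathway flags, plus trunk/major-branch target ranking and the end-to-end
# pipeline wrapper.

#' Annotate a clone tree into an epitope tree
#'
#' Per clone, counts distinct mutated genes and the subset harboring
#' putative neo-epitopes (gene-level counting, mirroring the usual
#' "mutated genes / epitope genes" clone labels); genes belonging to
#' significant pathways are flagged, with an additional marker when a
#' flagged gene also harbors an epitope. Clones are tiered: trunk =
#' ancestor clones; major branch = a descendant clone whose subtree holds
#' at least `major_branch_fraction` of the tumor's non-ancestor
#' mutations; everything else is a leaf.
#'
#' @param tree A `clone_tree`.
#' @param assignments Data frame `key, gene, clone` mapping every mutation
#'   to a clone of the tree.
#' @param epitope_calls Data frame `key, immunogenic, n_windows` (from
#'   [call_epitopes()]); mutations absent from it count as non-epitope.
#' @param significant_pathways Named list of gene vectors (e.g. the
#'   significant rows of [run_enrichment()] resolved against the
#'   collection), or NULL.
#' @param major_branch_fraction Subtree share of non-ancestor mutations
#'   required for the major-branch tier.
#' @return Object of class `epitope_tree`.
#' @export
annotate_epitope_tree <- function(tree, assignments, epitope_calls,
                                  significant_pathways = NULL,
                                  major_branch_fraction = 0.5) {
  tree <- validate_clone_tree(tree)
  if (is.null(tree$label)) tree <- classify_clones(tree)
  need <- c("key", "gene", "clone")
  if (!all(need %in% names(assignments)))
    stop_format("assignments needs columns: %s", paste(need, collapse = ", "))
  unknown <- setdiff(unique(assignments$clone), tree$nodes)
  if (length(unknown) > 0)
    stop_validation("assignment references unknown clone(s): %s",
                    paste(unknown, collapse = ", "))
  calls <- epitope_calls[, intersect(c("key", "immunogenic", "n_windows"),
                                     names(epitope_calls)), drop = FALSE]
  a <- merge(assignments, calls, by = "key", all.x = TRUE, sort = FALSE)
  a$immunogenic[is.na(a$immunogenic)] <- FALSE
  a$n_windows[is.na(a$n_windows)] <- 0L

  pw_of_gene <- function(g) {
    if (is.null(significant_pathways)) return(character())
    names(significant_pathways)[vapply(significant_pathways,
                                       function(set) g %in% set, TRUE)]
  }
  clones <- setdiff(tree$nodes, tree$root)
  per_clone <- lapply(clones, function(cl) {
    sub <- a[a$clone == cl, , drop = FALSE]
    genes <- sort(unique(sub$gene))
    epi_genes <- sort(unique(sub$gene[sub$immunogenic]))
    pflag <- lapply(genes, pw_of_gene)
    names(pflag) <- genes
    pflag <- pflag[lengths(pflag) > 0]
    list(n_mutations = nrow(sub),
         genes = genes,
         epitope_genes = epi_genes,
         pathway_genes = pflag,
         pathway_epitope_genes = intersect(names(pflag), epi_genes))
  })
  names(per_clone) <- clones

  # subtree mutation loads for the major-branch tier
  subtree_load <- function(node) {
    kids <- names(tree$parent)[tree$parent == node]
    per_clone[[node]]$n_mutations + sum(vapply(kids, subtree_load, 0))
  }
  non_ancestor <- sum(vapply(clones[tree$label[clones] != "ancestor"],
                             function(cl) per_clone[[cl]]$n_mutations, 0))
  tier <- vapply(clones, function(cl) {
    lab <- tree$label[[cl]]
    if (lab == "ancestor") "trunk"
    else if (lab == "descendant" && non_ancestor > 0 &&
             subtree_load(cl) >= major_branch_fraction * non_ancestor)
      "major_branch"
    else "leaf"
  }, "")

  structure(list(tree = tree, clones = per_clone, tier = tier,
                 mutations = a), class = "epitope_tree")
}

#' @export
print.epitope_tree <- function(x, ...) {
  cat("Cancer neo-epitope tree\n")
  for (cl in names(x$clones)) {
    info <- x$clones[[cl]]
    cat(sprintf("  %s [%s, %s]: (%d/%d) mutated genes / epitope genes%s\n",
                cl, x$tree$label[[cl]], x$tier[[cl]],
                length(info$genes), length(info$epitope_genes),
                if (length(info$pathway_genes) > 0)
                  paste0("; pathway genes: ",
                         paste(names(info$pathway_genes), collapse = ", "))
                else ""))
  }
  invisible(x)
}

#' Rank immunotherapy target candidates on an epitope tree
#'
#' Deterministic total order implementing the trunk-first principle:
#' tier (trunk > major branch > leaf), then membership in a significant
#' pathway, then number of supporting epitope windows, then gene name and
#' mutation key.
#'
#' @param etree An `epitope_tree`.
#' @return Data frame `gene, key, clone, tier, pathways, n_windows`,
#'   best candidates first (immunogenic mutations only).
#' @export
rank_targets <- function(etree) {
  a <- etree$mutations[etree$mutations$immunogenic, , drop = FALSE]
  if (nrow(a) == 0)
    return(data.frame(gene = character(), key = character(),
                      clone = character(), tier = character(),
                      pathways = character(), n_windows = integer(),
                      stringsAsFactors = FALSE))
  pw <- vapply(seq_len(nrow(a)), function(i) {
    flags <- etree$clones[[a$clone[i]]]$pathway_genes[[a$gene[i]]]
    if (is.null(flags)) "" else paste(sort(flags), collapse = ",")
  }, "")
  df <- data.frame(gene = a$gene, key = a$key, clone = a$clone,
                   tier = etree$tier[a$clone],
                   pathways = pw, n_windows = a$n_windows,
                   stringsAsFactors = FALSE)
  tier_rank <- c(trunk = 1L, major_branch = 2L, leaf = 3L)
  df <- df[order(tier_rank[df$tier], pw == "", -df$n_windows, df$gene,
                 df$key), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Serialise an epitope tree to JSON
#' @param etree An `epitope_tree`.
#' @param path Optional output file.
#' @return JSON text.
#' @export
write_epitope_tree <- function(etree, path = NULL) {
  obj <- list(tree = jsonlite::fromJSON(tree_to_json(etree$tree)),
              tier = as.list(etree$tier),
              clones = lapply(etree$clones, function(info)
                list(n_mutations = info$n_mutations,
                     n_genes = length(info$genes),
                     n_epitope_genes = length(info$epitope_genes),
                     genes = info$genes,
                     epitope_genes = info$epitope_genes,
                     pathway_genes = info$pathway_genes,
                     pathway_epitope_genes = info$pathway_epitope_genes)))
  txt <- as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}

#' @noRd
run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(errorCondition(sprintf("pipeline stage '%s' failed: %s", name,
                                conditionMessage(e)),
                        class = c("neoepitree_stage_error",
                                  "neoepitree_error"))))
}

#' Run the full pipeline on a simulated cohort
#'
#' End-to-end composition: simulate a cohort (writing every input file),
#' read the inputs back through the package's own readers, filter
#' population variants, call neo-epitopes, reconstruct per-tumor clone
#' trees, run pathway enrichment, screen HPV reads, build each patient's
#' annotated epitope tree with ranked targets, and write per-patient and
#' cohort outputs plus a manifest under `out_dir`. With a fixed config
#' seed two runs are byte-identical.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created).
#' @param n_perm Permutations for pathway enrichment.
#' @param fdr_threshold Significance threshold on adjusted p.
#' @param epsilon Sum-rule slack for tree search.
#' @param k_max Maximum clusters considered per tumor.
#' @param quiet Suppress per-stage count messages.
#' @return Invisibly, a list with the cohort, per-patient results and the
#'   cohort report.
#' @export
run_pipeline <- function(config = sim_config(), out_dir, n_perm = 10000,
                         fdr_threshold = 0.1, epsilon = 0.05, k_max = 6,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  input_dir <- file.path(out_dir, "inputs")
  cohort <- run_stage("simulate", simulate_cohort(config, dir = input_dir))
  say("simulate: %d tumors written to %s", config$n_tumors, input_dir)

  proteome <- run_stage("load", read_fasta(file.path(input_dir,
                                                     "proteome.fasta")))
  collection <- run_stage("load", read_gmt(file.path(input_dir,
                                                     "pathways.gmt")))
  panel <- run_stage("load", read_panel(file.path(input_dir, "panel.tsv")))
  refs <- run_stage("load", read_fasta(file.path(input_dir,
                                                 "references.fasta")))
  host_ref <- refs[!grepl("^HPV", names(refs))]
  hpv_refs <- refs[grepl("^HPV", names(refs))]
  predictor <- make_mock_predictor(config$immunogenic_fraction,
                                   flank = config$flank,
                                   window_length = config$window_length,
                                   alleles = config$alleles)
  sample_ids <- names(cohort$tumors)

  filtered <- list()
  for (sid in sample_ids) {
    tab <- run_stage("load", read_mutation_table(
      file.path(input_dir, paste0(sid, ".mutations.tsv")), "tsv"))
    fl <- run_stage("filter",
                    filter_population_variants(tab, panel,
                                               config$maf_threshold))
    say("filter %s: %d in, %d kept, %d removed", sid, nrow(tab),
        nrow(fl$kept), nrow(fl$removed))
    filtered[[sid]] <- fl
  }
  kept_tables <- lapply(filtered, `[[`, "kept")

  # cohort summaries
  spectrum <- run_stage("spectrum", substitution_spectrum(kept_tables))
  recurrence <- run_stage("recurrence",
                          gene_recurrence(kept_tables,
                                          n_patients = length(sample_ids)))
  summary_counts <- run_stage("summary", cohort_summary(kept_tables))

  # pathway enrichment on nonsynonymously mutated genes
  gene_sets <- run_stage("enrich", cohort_gene_sets(kept_tables))
  enrichment <- run_stage("enrich",
                          run_enrichment(collection, gene_sets,
                                         n_perm = n_perm,
                                         fdr_threshold = fdr_threshold,
                                         seed = derive_seed(config$seed,
                                                            600000)))
  sig <- enrichment$pathway[enrichment$significant]
  sig_pathways <- lapply(collection$pathways[sig], intersect,
                         collection$universe)
  say("enrich: %d pathways tested, %d significant at FDR < %.2f",
      nrow(enrichment), length(sig), fdr_threshold)

  host_idx <- kmer_index(host_ref)
  hpv_idx <- kmer_index(hpv_refs)
  all_idx <- kmer_index(c(host_ref, hpv_refs))

  patients <- list()
  for (t in seq_along(sample_ids)) {
    sid <- sample_ids[t]
    kept <- kept_tables[[sid]]
    calls <- run_stage("epitopes",
                       call_epitopes(kept, proteome, config$alleles,
                                     predictor, flank = config$flank,
                                     window_length = config$window_length))
    say("epitopes %s: %d missense scored, %d immunogenic", sid,
        nrow(calls), sum(calls$immunogenic))
    nonsyn <- kept[kept$consequence %in% c("missense", "nonsense"), ,
                   drop = FALSE]
    tree <- run_stage("phylo",
                      fit_clone_tree(nonsyn, purity = config$purity,
                                     k_max = k_max, epsilon = epsilon,
                                     seed = derive_seed(config$seed,
                                                        500000 + t)))
    assignment <- tree$clusters$assignment
    assignments <- data.frame(key = names(assignment),
                              gene = nonsyn$gene[match(names(assignment),
                                                       nonsyn$key)],
                              clone = unname(assignment),
                              stringsAsFactors = FALSE)
    etree <- run_stage("tree",
                       annotate_epitope_tree(tree, assignments, calls,
                                             significant_pathways =
                                               sig_pathways))
    targets <- run_stage("tree", rank_targets(etree))

    reads_fa <- run_stage("hpv", read_fasta(
      file.path(input_dir, paste0(sid, ".reads.fasta"))))
    ids <- sub("/[12]$", "", names(reads_fa))
    pairs <- data.frame(pair_id = unique(ids),
                        read1 = unname(reads_fa[paste0(unique(ids), "/1")]),
                        read2 = unname(reads_fa[paste0(unique(ids), "/2")]),
                        stringsAsFactors = FALSE)
    gcounts <- run_stage("hpv", genotype_counts(
      c(pairs$read1, pairs$read2), host_idx, hpv_idx))
    evidence <- run_stage("hpv", detect_integration(
      pairs, host_ref, hpv_refs, index = all_idx))
    say("hpv %s: genotype counts [%s], %d integration evidence pair(s)",
        sid, paste(names(gcounts), gcounts, sep = "=", collapse = ", "),
        nrow(evidence))

    patients[[sid]] <- list(filtered = kept, calls = calls, tree = tree,
                            epitope_tree = etree, targets = targets,
                            genotype_counts = gcounts,
                            integration = evidence)
  }

  report <- build_cohort_report(patients, summary_counts, spectrum,
                                recurrence, enrichment)
  write_pipeline_outputs(out_dir, patients, report, spectrum, recurrence,
                         enrichment)
  invisible(list(cohort = cohort, patients = patients, report = report,
                 enrichment = enrichment))
}

#' @noRd
build_cohort_report <- function(patients, summary_counts, spectrum,
                                recurrence, enrichment) {
  per_patient <- lapply(patients, function(p) {
    s <- summary.clone_tree(p$tree)
    list(n_mutations = nrow(p$filtered),
         n_nonsynonymous = sum(p$filtered$consequence %in%
                                 c("missense", "nonsense")),
         n_missense = nrow(p$calls),
         n_immunogenic = sum(p$calls$immunogenic),
         n_clones = length(p$tree$nodes) - 1L,
         topology = s$topology[1],
         n_integration_evidence = nrow(p$integration))
  })
  get <- function(f) vapply(per_patient, function(z) as.numeric(z[[f]]), 0)
  list(per_patient = per_patient,
       means = list(mutations = mean(get("n_mutations")),
                    nonsynonymous = mean(get("n_nonsynonymous")),
                    missense = mean(get("n_missense")),
                    immunogenic = mean(get("n_immunogenic"))),
       totals = list(by_class = as.list(summary_counts$by_class),
                     total = summary_counts$total),
       spectrum = as.list(spectrum$frequency),
       n_significant_pathways = sum(enrichment$significant),
       top_recurrent_genes = utils::head(recurrence, 10))
}

#' @noRd
write_pipeline_outputs <- function(out_dir, patients, report, spectrum,
                                   recurrence, enrichment) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character()
  emit <- function(rel) manifest <<- c(manifest, rel)
  for (sid in names(patients)) {
    p <- patients[[sid]]
    pdir <- file.path(out_dir, sid)
    dir.create(pdir, showWarnings = FALSE)
    write_mutation_table(p$filtered, file.path(pdir, "filtered.tsv"), "tsv")
    emit(file.path(sid, "filtered.tsv"))
    utils::write.table(p$calls, file.path(pdir, "epitope_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(file.path(sid, "epitope_calls.tsv"))
    for (fmt in c("newick", "dot", "json")) {
      ext <- c(newick = "nwk", dot = "dot", json = "json")[[fmt]]
      write_tree(p$tree, fmt, file.path(pdir, paste0("clone_tree.", ext)))
      emit(file.path(sid, paste0("clone_tree.", ext)))
    }
    write_epitope_tree(p$epitope_tree,
                       file.path(pdir, "epitope_tree.json"))
    emit(file.path(sid, "epitope_tree.json"))
    utils::write.table(p$targets, file.path(pdir, "targets.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(file.path(sid, "targets.tsv"))
    utils::write.table(p$integration, file.path(pdir, "integration.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(file.path(sid, "integration.tsv"))
  }
  utils::write.table(recurrence, file.path(out_dir, "recurrence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  emit("recurrence.tsv")
  spec_df <- data.frame(class = names(spectrum$frequency),
                        frequency = unname(spectrum$frequency))
  utils::write.table(spec_df, file.path(out_dir, "spectrum.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  emit("spectrum.tsv")
  write_enrichment_table(enrichment, file.path(out_dir, "enrichment.tsv"))
  emit("enrichment.tsv")
  hpv_df <- do.call(rbind, lapply(names(patients), function(sid) {
    g <- patients[[sid]]$genotype_counts
    data.frame(sample_id = sid, t(as.matrix(g)),
               n_integration = nrow(patients[[sid]]$integration),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(hpv_df, file.path(out_dir, "hpv_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  emit("hpv_report.tsv")
  jsonlite::write_json(report, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  emit("summary.json")
  jsonlite::write_json(list(files = sort(manifest)),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
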