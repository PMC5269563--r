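# Permutation-null pathway-alteration enrichment.
#
# For each pathway, the observed statistic is the number of patients whose
# nonsynonymously mutated genes intersect the pathway. The null draws the
# same number of genes from the gene universe without replacement, 10,000
# times by default; the p-value is the proportion of null draws in which
# strictly more patients carry a mutation than under the real pathway.
# Benjamini-Hochberg adjustment is applied across tested pathways and a
# pathway is flagged significant at adjusted P < 0.1.

#' Construct a pathway collection
#'
#' @param pathways Named list of gene-symbol vectors (each non-empty).
#' @param universe Gene universe; defaults to the union of pathway genes.
#'   Pathway genes absent from a supplied universe are reported in the
#'   `missing` field; the universe must be at least as large as the
#'   largest pathway.
#' @return Object of class `pathway_collection` with fields `pathways`,
#'   `universe`, `missing`.
#' @export
pathway_collection <- function(pathways, universe = NULL) {
  if (length(pathways) == 0 || is.null(names(pathways)) ||
      any(!nzchar(names(pathways))))
    stop_validation("pathways must be a non-empty named list")
  pathways <- lapply(pathways, function(g) unique(trimws(as.character(g))))
  if (any(lengths(pathways) == 0))
    stop_validation("every pathway must be non-empty")
  all_genes <- sort(unique(unlist(pathways, use.names = FALSE)))
  universe <- if (is.null(universe)) all_genes
              else sort(unique(trimws(as.character(universe))))
  if (length(universe) < max(lengths(pathways)))
    stop_validation("universe (%d genes) smaller than the largest pathway (%d genes)",
                    length(universe), max(lengths(pathways)))
  structure(list(pathways = pathways, universe = universe,
                 missing = setdiff(all_genes, universe)),
            class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("Pathway collection: %d pathways over a %d-gene universe (%d pathway genes outside universe)\n",
              length(x$pathways), length(x$universe), length(x$missing)))
  invisible(x)
}

#' Number of patients altered in a gene set
#'
#' @param pathway_genes Character vector of gene symbols.
#' @param cohort_gene_sets List of per-patient mutated-gene sets.
#' @return Integer count of patients whose set intersects the pathway.
#' @export
observed_alteration_count <- function(pathway_genes, cohort_gene_sets) {
  sum(vapply(cohort_gene_sets,
             function(s) any(s %in% pathway_genes), logical(1)))
}

#' Permutation p-value for pathway alteration
#'
#' Draws random gene sets of the same size (after intersecting the pathway
#' with the universe) without replacement from the universe and reports
#' the proportion of draws in which strictly more patients carry a
#' mutation than observed. `exact = TRUE` enumerates every subset instead
#' of sampling (feasible for small universes), giving the exhaustive
#' strict-greater tail.
#'
#' @param pathway_genes Pathway gene symbols.
#' @param cohort_gene_sets List of per-patient mutated-gene sets.
#' @param universe Gene universe to sample from.
#' @param n_perm Number of random draws (default 10000).
#' @param seed Optional RNG seed.
#' @param exact Enumerate all subsets instead of sampling.
#' @param add_one Add-one (draw-inclusive) correction
#'   `(b + 1) / (n_perm + 1)`; off by default, matching the strict
#'   proportion definition.
#' @return Numeric p-value, or `NA` (with a warning) when the pathway has
#'   no gene in the universe. The observed count is attached as the
#'   `"observed"` attribute.
#' @export
permutation_pvalue <- function(pathway_genes, cohort_gene_sets, universe,
                               n_perm = 10000, seed = NULL, exact = FALSE,
                               add_one = FALSE) {
  if (!exact && n_perm < 1) stop_validation("n_perm must be >= 1")
  genes <- intersect(pathway_genes, universe)
  m <- length(genes)
  if (m == 0) {
    warning("pathway has no genes in the universe; p-value undefined")
    return(structure(NA_real_, observed = NA_integer_))
  }
  observed <- observed_alteration_count(genes, cohort_gene_sets)
  # patient-hit matrix: genes x patients membership, counts via any()
  M <- vapply(cohort_gene_sets, function(s) universe %in% s,
              logical(length(universe)))
  M <- matrix(M, nrow = length(universe))
  count_for <- function(idx) {
    if (length(idx) == 1) sum(M[idx, ]) else sum(colSums(M[idx, , drop = FALSE]) > 0)
  }
  if (exact) {
    if (choose(length(universe), m) > 5e5)
      stop_validation("exact enumeration infeasible: choose(%d, %d) subsets",
                      length(universe), m)
    subsets <- utils::combn(length(universe), m)
    counts <- apply(subsets, 2, count_for)
    p <- mean(counts > observed)
  } else {
    exceed <- with_seed(seed, {
      e <- 0L
      for (b in seq_len(n_perm)) {
        idx <- sample.int(length(universe), m)
        if (count_for(idx) > observed) e <- e + 1L
      }
      e
    })
    p <- if (add_one) (exceed + 1) / (n_perm + 1) else exceed / n_perm
  }
  structure(p, observed = observed)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment (via [stats::p.adjust()]),
#' preserving input order.
#'
#' @param pvalues Numeric vector in \[0, 1\] (NAs passed through).
#' @return Adjusted values in input order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop_validation("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Mutated-gene sets per patient
#'
#' Helper building the per-patient nonsynonymously mutated gene sets the
#' enrichment test consumes.
#'
#' @param tables Mutation table or list of tables.
#' @param classes Consequence classes counted as altering a gene.
#' @return Named list of gene-symbol vectors, one per patient.
#' @export
cohort_gene_sets <- function(tables,
                             classes = c("missense", "nonsense",
                                         "deletion", "insertion")) {
  tab <- if (is.data.frame(tables)) tables else do.call(rbind, tables)
  tab <- validate_mutation_table(tab)
  tab <- tab[tab$consequence %in% classes & !is.na(tab$gene), , drop = FALSE]
  lapply(split(tab$gene, tab$sample_id), unique)
}

#' Run the pathway-alteration enrichment test
#'
#' One permutation test per pathway with at least one universe gene,
#' Benjamini-Hochberg adjustment across the tested pathways (m = number of
#' tested pathways), results sorted by p ascending.
#'
#' @param collection A `pathway_collection`.
#' @param gene_sets Per-patient mutated-gene sets (see
#'   [cohort_gene_sets()]).
#' @param n_perm Permutations per pathway.
#' @param fdr_threshold Significance threshold on the adjusted p.
#' @param seed Optional RNG seed; per-pathway substreams are derived from
#'   it so results do not depend on pathway order.
#' @return Data frame of class `pathway_results`: `pathway, n_genes,
#'   n_patients_altered, p_value, fdr, significant`.
#' @export
run_enrichment <- function(collection, gene_sets, n_perm = 10000,
                           fdr_threshold = 0.1, seed = NULL) {
  if (!inherits(collection, "pathway_collection"))
    stop_validation("collection must be a pathway_collection")
  keep <- vapply(collection$pathways, function(g)
    length(intersect(g, collection$universe)) > 0, logical(1))
  pathways <- collection$pathways[keep]
  nm <- names(pathways)
  res <- data.frame(pathway = nm,
                    n_genes = vapply(pathways, function(g)
                      length(intersect(g, collection$universe)), 0L),
                    n_patients_altered = NA_integer_,
                    p_value = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(pathways)) {
    p <- permutation_pvalue(pathways[[i]], gene_sets, collection$universe,
                            n_perm = n_perm,
                            seed = if (is.null(seed)) NULL
                                   else derive_seed(seed, i))
    res$n_patients_altered[i] <- attr(p, "observed")
    res$p_value[i] <- as.numeric(p)
  }
  res$fdr <- bh_adjust(res$p_value)
  res$significant <- !is.na(res$fdr) & res$fdr < fdr_threshold
  res <- res[order(res$p_value, res$pathway), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_perm") <- n_perm
  class(res) <- c("pathway_results", "data.frame")
  res
}

#' Export enrichment results as a TSV table
#'
#' Columns mirror the usual published layout (pathway, number of patients
#' altered, P value, FDR); `p = 0` is printed as `< 1/n_perm`.
#'
#' @param results A `pathway_results` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_table <- function(results, path) {
  n_perm <- attr(results, "n_perm") %||% NA
  p_txt <- ifelse(results$p_value == 0 & !is.na(n_perm),
                  paste0("<", format(1 / n_perm, scientific = FALSE)),
                  format(results$p_value, trim = TRUE, scientific = FALSE))
  df <- data.frame(pathway = results$pathway,
                   n_genes = results$n_genes,
                   patients_altered = results$n_patients_altered,
                   p_value = p_txt,
                   fdr = format(results$fdr, trim = TRUE,
                                scientific = FALSE),
                   significant = results$significant,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
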