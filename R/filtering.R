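# Post-calling cleanup and cohort summaries: population-panel removal of
# likely germline polymorphisms, a minimal codon-level consequence
# annotator, the directed substitution spectrum, gene recurrence across
# patients, and consequence-class totals.

#' Construct a population variant panel
#'
#' A panel maps variant keys (chrom, pos, ref, alt) to population minor
#' allele frequencies, as distributed by resources like the 1000 Genomes
#' Project, ESP or ExAC.
#'
#' @param df Data frame with columns `chrom, pos, ref, alt, maf`.
#' @param name Panel name.
#' @return Object of class `population_panel`.
#' @export
population_panel <- function(df, name = "panel") {
  need <- c("chrom", "pos", "ref", "alt", "maf")
  if (!all(need %in% names(df)))
    stop_format("panel needs columns: %s", paste(need, collapse = ", "))
  df$maf <- as.numeric(df$maf)
  if (any(is.na(df$maf) | df$maf < 0 | df$maf > 1))
    stop_validation("panel MAF outside [0, 1]")
  structure(list(name = name,
                 maf = stats::setNames(df$maf,
                                       mutation_key(df$chrom, df$pos,
                                                    df$ref, df$alt))),
            class = "population_panel")
}

#' Read a population panel from TSV
#'
#' @param path TSV with columns `chrom, pos, ref, alt, maf`.
#' @param name Panel name (defaults to the file name).
#' @return A `population_panel`.
#' @export
read_panel <- function(path, name = NULL) {
  if (!file.exists(path)) stop_format("no such file: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  population_panel(df, name = name %||% basename(path))
}

#' Write a population panel to TSV
#' @param panel A `population_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  parts <- strsplit(names(panel$maf), ":", fixed = TRUE)
  df <- data.frame(chrom = vapply(parts, `[[`, "", 1),
                   pos = as.integer(vapply(parts, `[[`, "", 2)),
                   ref = vapply(parts, `[[`, "", 3),
                   alt = vapply(parts, `[[`, "", 4),
                   maf = unname(panel$maf), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove population polymorphisms from somatic calls
#'
#' A mutation is removed iff some panel contains its (chrom, pos, ref, alt)
#' key with MAF at or above `maf_threshold`; kept and removed partition the
#' input with order preserved.
#'
#' @param tab Mutation table.
#' @param panels A `population_panel` or list of panels.
#' @param maf_threshold Removal threshold (default 0.1).
#' @return List with `kept` and `removed` mutation tables.
#' @export
filter_population_variants <- function(tab, panels, maf_threshold = 0.1) {
  if (maf_threshold < 0 || maf_threshold > 1)
    stop_validation("maf_threshold must be in [0, 1]")
  tab <- validate_mutation_table(tab)
  if (inherits(panels, "population_panel")) panels <- list(panels)
  hit <- rep(FALSE, nrow(tab))
  for (panel in panels) {
    maf <- panel$maf[tab$key]
    hit <- hit | (!is.na(maf) & maf >= maf_threshold)
  }
  list(kept = tab[!hit, , drop = FALSE], removed = tab[hit, , drop = FALSE])
}

#' Classify the protein consequence of an SNV against a coding sequence
#'
#' Minimal codon annotator for in-frame coding sequences: the codon is
#' read at `(pos - 1) %/% 3` (1-based `pos` within the CDS), the reference
#' and alternate codons are translated with the standard genetic code, and
#' the change is labelled synonymous (same residue), missense (different
#' residue), nonsense (stop gained) or other (stop lost / start codon);
#' length-changing alleles are deletions/insertions.
#'
#' @param coding_sequence In-frame CDS (string over ACGT; length a multiple
#'   of 3).
#' @param pos 1-based position of the variant within the CDS.
#' @param ref,alt Reference and alternate alleles.
#' @return One of `synonymous, missense, nonsense, deletion, insertion,
#'   other`.
#' @export
classify_consequence <- function(coding_sequence, pos, ref, alt) {
  if (nchar(ref) != nchar(alt))
    return(if (nchar(ref) > nchar(alt)) "deletion" else "insertion")
  if (nchar(ref) != 1) return("other")
  L <- nchar(coding_sequence)
  if (pos < 1 || pos > L)
    stop_validation("pos %d outside coding sequence (length %d)", pos, L)
  found <- substr(coding_sequence, pos, pos)
  if (found != ref)
    stop_validation("reference mismatch at CDS position %d: sequence has %s, variant says %s",
                    pos, found, ref)
  codon_start <- pos - (pos - 1) %% 3
  codon_ref <- substr(coding_sequence, codon_start, codon_start + 2)
  if (nchar(codon_ref) < 3) return("other")
  codon_alt <- codon_ref
  substr(codon_alt, (pos - 1) %% 3 + 1, (pos - 1) %% 3 + 1) <- alt
  aa_ref <- translate_codon(codon_ref)
  aa_alt <- translate_codon(codon_alt)
  if (aa_ref == aa_alt) "synonymous"
  else if (aa_alt == "*") "nonsense"
  else if (aa_ref == "*") "other"
  else "missense"
}

#' @noRd
translate_codon <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  aa <- code[[toupper(codon)]]
  if (is.null(aa)) stop_validation("not a codon: %s", codon)
  aa
}

#' Directed base-substitution spectrum
#'
#' Frequencies of the 12 directed ref>alt single-nucleotide substitution
#' classes (no strand collapsing, so C>T and G>A are reported separately),
#' normalised to sum to 1 over the cohort, plus the per-patient frequency
#' matrix. Non-SNV records are skipped and counted.
#'
#' @param tables A mutation table or list of tables.
#' @return List with `frequency` (named 12-vector summing to 1),
#'   `per_patient` (patients x 12 matrix of frequencies), `n_skipped`.
#' @export
substitution_spectrum <- function(tables) {
  tab <- if (is.data.frame(tables)) tables else do.call(rbind, tables)
  tab <- validate_mutation_table(tab)
  bases <- c("A", "C", "G", "T")
  classes <- unlist(lapply(bases, function(r)
    paste0(r, ">", setdiff(bases, r))))
  is_snv <- tab$ref %in% bases & tab$alt %in% bases
  n_skipped <- sum(!is_snv)
  snv <- tab[is_snv, , drop = FALSE]
  if (nrow(snv) == 0) stop_validation("no SNVs to tabulate")
  cls <- factor(paste0(snv$ref, ">", snv$alt), levels = classes)
  counts <- table(cls)
  per_patient <- t(vapply(split(cls, snv$sample_id), function(z)
    as.numeric(table(z)) / length(z), numeric(12)))
  colnames(per_patient) <- classes
  list(frequency = stats::setNames(as.numeric(counts) / nrow(snv), classes),
       per_patient = per_patient,
       n_skipped = n_skipped)
}

#' Gene recurrence across patients
#'
#' A patient counts once per gene regardless of how many mutations it
#' carries there; percent is `100 * count / n_patients` rounded half-up to
#' one decimal (so 4 of 23 patients prints 17.4).
#'
#' @param tables A mutation table or list of per-patient tables.
#' @param n_patients Number of patients in the cohort (defaults to the
#'   number of distinct `sample_id`s present).
#' @param min_patients Keep genes mutated in at least this many patients.
#' @return Data frame `gene, n_patients, percent`, sorted by count
#'   descending then gene name.
#' @export
gene_recurrence <- function(tables, n_patients = NULL, min_patients = 1) {
  tab <- if (is.data.frame(tables)) tables else do.call(rbind, tables)
  tab <- validate_mutation_table(tab)
  n_patients <- n_patients %||% length(unique(tab$sample_id))
  if (n_patients < 1) stop_validation("n_patients must be >= 1")
  pairs <- unique(tab[!is.na(tab$gene) & nzchar(tab$gene),
                      c("gene", "sample_id")])
  counts <- table(pairs$gene)
  df <- data.frame(gene = names(counts), n_patients = as.integer(counts),
                   stringsAsFactors = FALSE)
  df$percent <- round_half_up(100 * df$n_patients / n_patients, 1)
  df <- df[df$n_patients >= min_patients, , drop = FALSE]
  df <- df[order(-df$n_patients, df$gene), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Cohort totals by consequence class
#'
#' @param tables A mutation table or list of tables.
#' @return List with `by_class` (named counts over the consequence
#'   classes), `total`, and `per_patient` (named totals).
#' @export
cohort_summary <- function(tables) {
  tab <- if (is.data.frame(tables)) tables else do.call(rbind, tables)
  if (nrow(tab) == 0)
    return(list(by_class = stats::setNames(rep(0L, length(CONSEQUENCE_LEVELS)),
                                           CONSEQUENCE_LEVELS),
                total = 0L, per_patient = integer()))
  tab <- validate_mutation_table(tab)
  by_class <- table(factor(tab$consequence, levels = CONSEQUENCE_LEVELS))
  per_patient <- table(tab$sample_id)
  list(by_class = stats::setNames(as.integer(by_class),
                                  CONSEQUENCE_LEVELS),
       total = nrow(tab),
       per_patient = stats::setNames(as.integer(per_patient),
                                     names(per_patient)))
}
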