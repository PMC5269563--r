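# Neo-epitope calling from mutant versus wild-type peptide binding.
#
# For a somatic missense mutation, the mutated residue is taken with eight
# flanking residues on each side (a 17-mer inside the protein body,
# truncated at termini). MHC class I presents short peptides, so fixed-
# length windows (9-mers by default, configurable 8-11) containing the
# mutated residue are slid across the pair, mutant and wild-type windows
# sharing identical start coordinates. A mutation is called immunogenic if
# for some HLA allele and window the mutant peptide binds strongly
# (affinity < 50 nM) while the wild-type peptide at the same position does
# not bind (affinity > 500 nM). Affinity prediction is a pluggable
# `function(peptide, allele) -> nM` (IC50, lower = stronger).

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Extract the mutant/wild-type peptide pair around a missense mutation
#'
#' The window is `[max(1, pos - flank), min(L, pos + flank)]` on the
#' protein (1-based, closed); the mutant sequence differs from the
#' wild-type only at the mutated residue.
#'
#' @param protein_sequence Wild-type protein sequence (single string).
#' @param protein_pos 1-based mutated residue position.
#' @param aa_ref,aa_alt Reference and alternate residues (must differ).
#' @param flank Residues kept on each side of the mutation (default 8,
#'   giving a 17-mer away from the termini).
#' @param protein_id Optional identifier used in error messages.
#' @return Object of class `peptide_pair` with fields `wild_type`,
#'   `mutant`, `mutated_offset` (1-based within the peptide),
#'   `protein_id`, `flank`.
#' @export
extract_peptide_pair <- function(protein_sequence, protein_pos, aa_ref,
                                 aa_alt, flank = 8, protein_id = NULL) {
  L <- nchar(protein_sequence)
  if (protein_pos < 1 || protein_pos > L)
    stop_validation("protein_pos %d outside protein %s (length %d)",
                    protein_pos, protein_id %||% "?", L)
  if (aa_ref == aa_alt)
    stop_validation("aa_ref equals aa_alt (%s); not a missense change", aa_ref)
  found <- substr(protein_sequence, protein_pos, protein_pos)
  if (found != aa_ref)
    stop(errorCondition(
      sprintf("annotation inconsistency in protein %s: residue %d is %s, annotated aa_ref is %s",
              protein_id %||% "?", protein_pos, found, aa_ref),
      class = c("neoepitree_annotation_error", "neoepitree_error")))
  start <- max(1, protein_pos - flank)
  end <- min(L, protein_pos + flank)
  wt <- substr(protein_sequence, start, end)
  offset <- protein_pos - start + 1L
  mut <- wt
  substr(mut, offset, offset) <- aa_alt
  structure(list(wild_type = wt, mutant = mut, mutated_offset = offset,
                 protein_id = protein_id, flank = flank),
            class = "peptide_pair")
}

#' Enumerate aligned fixed-length windows over a peptide pair
#'
#' All windows of `window_length` that contain the mutated residue; mutant
#' and wild-type windows are taken at identical starts ("the same peptide
#' position"). A peptide shorter than the window yields no windows.
#'
#' @param pair A `peptide_pair`.
#' @param window_length MHC-I window length (8-11; default 9).
#' @return Data frame with `window_start` (1-based within the peptide),
#'   `mutant`, `wild_type`; zero rows when the peptide is too short.
#' @export
enumerate_windows <- function(pair, window_length = 9) {
  if (window_length < 8 || window_length > 11)
    stop_validation("window_length must be in 8..11")
  L <- nchar(pair$wild_type)
  off <- pair$mutated_offset
  if (L < window_length)
    return(data.frame(window_start = integer(), mutant = character(),
                      wild_type = character(), stringsAsFactors = FALSE))
  starts <- max(1, off - window_length + 1):min(off, L - window_length + 1)
  data.frame(window_start = starts,
             mutant = substring(pair$mutant, starts,
                                starts + window_length - 1),
             wild_type = substring(pair$wild_type, starts,
                                   starts + window_length - 1),
             stringsAsFactors = FALSE)
}

#' Call immunogenicity of one peptide pair
#'
#' Applies the binding rule over the full window-by-allele grid: the
#' mutation is immunogenic iff some allele and window has mutant affinity
#' < `strong` nM and wild-type affinity > `weak` nM at the same window
#' start. All qualifying windows are recorded. A predictor failure on any
#' window aborts the call (no partial silent results).
#'
#' @param pair A `peptide_pair`.
#' @param alleles Character vector of HLA allele names.
#' @param predictor `function(peptide, allele)` returning affinity in nM;
#'   must accept vectorised `peptide`.
#' @param strong Strong-binder threshold for the mutant (nM).
#' @param weak No-binding threshold for the wild-type (nM).
#' @param window_length Window length passed to [enumerate_windows()].
#' @param key Optional mutation key carried into the result.
#' @return Object of class `immunogenicity_call`: `key`, `immunogenic`
#'   (logical), and `windows`, a data frame of qualifying
#'   `(allele, window_start, window_length, mutant_nM, wildtype_nM)` rows.
#' @export
call_immunogenic <- function(pair, alleles, predictor, strong = 50,
                             weak = 500, window_length = 9, key = NULL) {
  win <- enumerate_windows(pair, window_length)
  rows <- list()
  for (allele in alleles) {
    if (nrow(win) == 0) break
    mut_nM <- tryCatch(predictor(win$mutant, allele), error = function(e)
      stop_validation("affinity predictor failed on allele %s: %s", allele,
                      conditionMessage(e)))
    wt_nM <- tryCatch(predictor(win$wild_type, allele), error = function(e)
      stop_validation("affinity predictor failed on allele %s: %s", allele,
                      conditionMessage(e)))
    if (length(mut_nM) != nrow(win) || length(wt_nM) != nrow(win) ||
        any(!is.finite(mut_nM)) || any(!is.finite(wt_nM)))
      stop_validation("affinity predictor returned a malformed result for allele %s",
                      allele)
    hit <- mut_nM < strong & wt_nM > weak
    if (any(hit))
      rows[[length(rows) + 1L]] <- data.frame(
        allele = allele, window_start = win$window_start[hit],
        window_length = window_length, mutant_nM = mut_nM[hit],
        wildtype_nM = wt_nM[hit], stringsAsFactors = FALSE)
  }
  windows <- if (length(rows) > 0) do.call(rbind, rows)
             else data.frame(allele = character(), window_start = integer(),
                             window_length = integer(), mutant_nM = numeric(),
                             wildtype_nM = numeric(), stringsAsFactors = FALSE)
  structure(list(key = key, immunogenic = nrow(windows) > 0,
                 windows = windows),
            class = "immunogenicity_call")
}

#' @export
print.immunogenicity_call <- function(x, ...) {
  cat(sprintf("Immunogenicity call%s: %s (%d supporting window(s))\n",
              if (is.null(x$key)) "" else paste0(" for ", x$key),
              if (x$immunogenic) "immunogenic" else "not immunogenic",
              nrow(x$windows)))
  invisible(x)
}

#' Score every missense mutation of a cohort
#'
#' Only missense mutations are scored; nonsense and indel mutations never
#' yield epitope calls. The protein for a mutation is looked up in
#' `proteome` by transcript first, then by gene symbol; mutations with no
#' matching protein are skipped and reported in the `"skipped"` attribute.
#'
#' @param tab Mutation table (one or more samples).
#' @param proteome Named character vector of protein sequences (from
#'   [read_fasta()]).
#' @param alleles HLA alleles to score.
#' @param predictor Affinity predictor `function(peptide, allele) -> nM`.
#' @param flank,window_length,strong,weak See [extract_peptide_pair()] and
#'   [call_immunogenic()].
#' @return Data frame with one row per missense mutation: `sample_id`,
#'   `key`, `gene`, `immunogenic`, `n_windows`.
#' @export
call_epitopes <- function(tab, proteome, alleles, predictor, flank = 8,
                          window_length = 9, strong = 50, weak = 500) {
  tab <- validate_mutation_table(tab)
  mis <- tab[tab$consequence == "missense", , drop = FALSE]
  skipped <- character()
  out <- vector("list", nrow(mis))
  for (i in seq_len(nrow(mis))) {
    pid <- if (!is.na(mis$transcript[i]) && mis$transcript[i] %in% names(proteome))
      mis$transcript[i]
    else if (mis$gene[i] %in% names(proteome)) mis$gene[i]
    else NA_character_
    if (is.na(pid)) {
      skipped <- c(skipped, mis$key[i])
      next
    }
    pair <- extract_peptide_pair(proteome[[pid]], mis$protein_pos[i],
                                 mis$aa_ref[i], mis$aa_alt[i], flank = flank,
                                 protein_id = pid)
    call <- call_immunogenic(pair, alleles, predictor, strong = strong,
                             weak = weak, window_length = window_length,
                             key = mis$key[i])
    out[[i]] <- data.frame(sample_id = mis$sample_id[i], key = mis$key[i],
                           gene = mis$gene[i], immunogenic = call$immunogenic,
                           n_windows = nrow(call$windows),
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  res <- if (length(out) > 0) do.call(rbind, out)
         else data.frame(sample_id = character(), key = character(),
                         gene = character(), immunogenic = logical(),
                         n_windows = integer(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}

#' Per-patient nonsynonymous and immunogenic mutation counts
#'
#' @inheritParams call_epitopes
#' @param tables A single mutation table or a list of per-sample tables.
#' @return Data frame with one row per patient: `sample_id`,
#'   `n_nonsynonymous` (missense + nonsense substitutions), `n_missense`,
#'   `n_immunogenic`; cohort means in the `"means"` attribute.
#' @export
cohort_epitope_counts <- function(tables, proteome, alleles, predictor,
                                  flank = 8, window_length = 9, strong = 50,
                                  weak = 500) {
  tab <- if (is.data.frame(tables)) tables else do.call(rbind, tables)
  tab <- validate_mutation_table(tab)
  calls <- call_epitopes(tab, proteome, alleles, predictor, flank = flank,
                         window_length = window_length, strong = strong,
                         weak = weak)
  samples <- unique(tab$sample_id)
  res <- do.call(rbind, lapply(samples, function(s) {
    sub <- tab[tab$sample_id == s, , drop = FALSE]
    sc <- calls[calls$sample_id == s, , drop = FALSE]
    data.frame(sample_id = s,
               n_nonsynonymous = sum(sub$consequence %in%
                                       c("missense", "nonsense")),
               n_missense = sum(sub$consequence == "missense"),
               n_immunogenic = sum(sc$immunogenic),
               stringsAsFactors = FALSE)
  }))
  stopifnot(all(res$n_immunogenic <= res$n_missense),
            all(res$n_missense <= res$n_nonsynonymous))
  attr(res, "means") <- c(n_nonsynonymous = mean(res$n_nonsynonymous),
                          n_missense = mean(res$n_missense),
                          n_immunogenic = mean(res$n_immunogenic))
  attr(res, "calls") <- calls
  res
}
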