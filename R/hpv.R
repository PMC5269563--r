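# HPV genotyping and integration screening.
#
# A naive seed-and-extend matcher assigns reads to small references (a host
# contig and ~8 kb HPV genomes): exact k-mer seeds (k = 31 by default)
# against an indexed reference set, ungapped extension at the implied
# offset, best reference by matched fraction, searched on both strands;
# a read is unmapped when its best matched fraction falls below 0.8.
# Integration evidence is a read pair with one end matching the host and
# the other an HPV genotype. Breakpoints are not refined: evidence stays
# at pair granularity.

#' Reverse complement of DNA strings
#' @param x Character vector of ACGTN sequences.
#' @return Reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
          collapse = ""), "", USE.NAMES = FALSE)
}

#' Build a k-mer index over a reference set
#'
#' @param references Named character vector of reference sequences.
#' @param k Seed length.
#' @return Object of class `kmer_index` (environment keyed by k-mer, each
#'   value a list of `(reference, position)` seed hits).
#' @export
kmer_index <- function(references, k = 31) {
  if (inherits(references, "kmer_index")) return(references)
  if (length(references) == 0) stop_validation("empty reference set")
  if (is.null(names(references)) || any(!nzchar(names(references))))
    stop_validation("references must be named")
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (nm in names(references)) {
    seq <- toupper(references[[nm]])
    L <- nchar(seq)
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    kmers <- substring(seq, starts, starts + k - 1L)
    first <- !duplicated(kmers)   # one seed per distinct k-mer per reference
    for (i in which(first)) {
      key <- kmers[i]
      env[[key]] <- c(env[[key]], list(c(nm, starts[i])))
    }
  }
  structure(list(env = env, k = k, references = references),
            class = "kmer_index")
}

#' @noRd
ungapped_matched_fraction <- function(read, ref_seq, align_start) {
  n <- nchar(read)
  L <- nchar(ref_seq)
  lo <- max(1L, align_start)
  hi <- min(L, align_start + n - 1L)
  if (hi < lo) return(0)
  ref_part <- utf8ToInt(substr(ref_seq, lo, hi))
  read_part <- utf8ToInt(substr(read, lo - align_start + 1L,
                                hi - align_start + 1L))
  sum(ref_part == read_part) / n   # off-reference bases count as mismatch
}

#' Match a read against indexed references
#'
#' Seed-and-extend: exact k-mer seeds are looked up at several read
#' offsets (both strands), each seed implies an ungapped alignment offset,
#' and the best reference by matched fraction wins. The read is unmapped
#' when the best fraction is below `min_matched_fraction` (its
#' matched_fraction is then reported as 0).
#'
#' @param read_sequence Read (length >= k).
#' @param references Named character vector of references, or a prebuilt
#'   [kmer_index()].
#' @param k Seed length (ignored when an index is supplied).
#' @param min_matched_fraction Acceptance threshold on the fraction of
#'   matching bases.
#' @param hpv_pattern Regex classifying reference names as HPV.
#' @return List `(target_class, reference, position, matched_fraction,
#'   strand)`; `position` is the 1-based reference position of the read's
#'   first base.
#' @export
match_read <- function(read_sequence, references, k = 31,
                       min_matched_fraction = 0.8, hpv_pattern = "^HPV") {
  idx <- if (inherits(references, "kmer_index")) references
         else kmer_index(references, k)
  k <- idx$k
  read_sequence <- toupper(read_sequence)
  n <- nchar(read_sequence)
  if (n < k) stop_validation("read length %d below seed length %d", n, k)
  best <- list(frac = 0, ref = NA_character_, pos = NA_integer_,
               strand = NA_character_)
  # overlapping seeds (step k/2) keep the chance that every seed straddles
  # a sequencing error negligible at ~1% substitution rates
  offsets <- unique(c(seq(1L, n - k + 1L, by = max(1L, k %/% 2L)),
                      n - k + 1L))
  for (strand in c("+", "-")) {
    oriented <- if (strand == "+") read_sequence else revcomp(read_sequence)
    seen <- character()
    for (off in offsets) {
      seed <- substr(oriented, off, off + k - 1L)
      hits <- idx$env[[seed]]
      if (is.null(hits)) next
      for (h in hits) {
        tag <- paste(strand, h[1], as.integer(h[2]) - off + 1L)
        if (tag %in% seen) next
        seen <- c(seen, tag)
        align_start <- as.integer(h[2]) - off + 1L
        frac <- ungapped_matched_fraction(oriented, idx$references[[h[1]]],
                                          align_start)
        if (frac > best$frac) best <- list(frac = frac, ref = h[1],
                                           pos = align_start, strand = strand)
      }
    }
    if (best$frac == 1) break
  }
  if (best$frac < min_matched_fraction)
    return(list(target_class = "unmapped", reference = "*",
                position = NA_integer_, matched_fraction = 0,
                strand = NA_character_))
  list(target_class = infer_target_class(best$ref, hpv_pattern),
       reference = best$ref, position = best$pos,
       matched_fraction = best$frac, strand = best$strand)
}

#' Per-genotype read counts from host-unmatched reads
#'
#' Emulates the screening step in which reads failing to map to the host
#' genome are realigned against a panel of HPV reference genomes: only
#' reads that do not match the host are counted, one count per best-
#' matching genotype, with zero-count genotypes listed.
#'
#' @param reads Character vector of read sequences.
#' @param host_ref Named character vector with the host reference(s), or a
#'   prebuilt [kmer_index()].
#' @param hpv_refs Named character vector of HPV genotype references, or a
#'   prebuilt [kmer_index()].
#' @param k,min_matched_fraction Matcher parameters.
#' @return Named integer vector of read counts per HPV genotype (plus
#'   `host` and `unmapped` tallies in the `"other"` attribute).
#' @export
genotype_counts <- function(reads, host_ref, hpv_refs, k = 31,
                            min_matched_fraction = 0.8) {
  host_idx <- kmer_index(host_ref, k)
  hpv_idx <- kmer_index(hpv_refs, k)
  counts <- stats::setNames(integer(length(hpv_idx$references)),
                            names(hpv_idx$references))
  n_host <- 0L
  n_unmapped <- 0L
  for (read in reads) {
    h <- match_read(read, host_idx,
                    min_matched_fraction = min_matched_fraction)
    if (h$target_class != "unmapped") {
      n_host <- n_host + 1L
      next
    }
    v <- match_read(read, hpv_idx,
                    min_matched_fraction = min_matched_fraction)
    if (v$target_class == "unmapped") n_unmapped <- n_unmapped + 1L
    else counts[[v$reference]] <- counts[[v$reference]] + 1L
  }
  attr(counts, "other") <- c(host = n_host, unmapped = n_unmapped)
  counts
}

#' Detect candidate HPV integration events from read pairs
#'
#' A pair yields evidence iff one end matches the host and the other
#' matches any HPV genotype, both at or above `min_matched_fraction`.
#'
#' @param read_pairs Data frame with columns `pair_id, read1, read2`
#'   (sequences).
#' @param host_ref,hpv_refs Named reference vectors.
#' @param k,min_matched_fraction Matcher parameters.
#' @param index Optional prebuilt [kmer_index()] over host and HPV
#'   references together (saves rebuilding across tumors).
#' @return Data frame of class `integration_evidence`, sorted by
#'   `pair_id`: `pair_id, host_ref, host_pos, hpv_genotype, hpv_pos`.
#' @export
detect_integration <- function(read_pairs, host_ref, hpv_refs, k = 31,
                               min_matched_fraction = 0.8, index = NULL) {
  need <- c("pair_id", "read1", "read2")
  if (!all(need %in% names(read_pairs)))
    stop_format("read_pairs needs columns: %s", paste(need, collapse = ", "))
  idx <- index %||% kmer_index(c(host_ref, hpv_refs), k)
  out <- list()
  for (i in seq_len(nrow(read_pairs))) {
    m1 <- match_read(read_pairs$read1[i], idx,
                     min_matched_fraction = min_matched_fraction)
    m2 <- match_read(read_pairs$read2[i], idx,
                     min_matched_fraction = min_matched_fraction)
    classes <- c(m1$target_class, m2$target_class)
    if (setequal(classes, c("host", "hpv"))) {
      host_end <- if (m1$target_class == "host") m1 else m2
      hpv_end <- if (m1$target_class == "hpv") m1 else m2
      out[[length(out) + 1L]] <- data.frame(
        pair_id = read_pairs$pair_id[i],
        host_ref = host_end$reference, host_pos = host_end$position,
        hpv_genotype = hpv_end$reference, hpv_pos = hpv_end$position,
        stringsAsFactors = FALSE)
    }
  }
  ev <- if (length(out) > 0) do.call(rbind, out)
        else data.frame(pair_id = character(), host_ref = character(),
                        host_pos = integer(), hpv_genotype = character(),
                        hpv_pos = integer(), stringsAsFactors = FALSE)
  ev <- ev[order(ev$pair_id), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("integration_evidence", "data.frame")
  ev
}
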