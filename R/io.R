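# Readers and writers for the standard formats the pipeline touches:
# mutation tables (MAF-like TSV and a single-sample VCF dialect), GMT gene
# sets, FASTA, minimal SAM / TSV read pairs, and clone-tree serialisation
# (Newick, DOT, JSON). All genomic and protein coordinates are 1-based and
# closed, in every reader and writer.

MUTATION_COLUMNS <- c("chrom", "pos", "ref", "alt", "gene", "protein_pos",
                      "aa_ref", "aa_alt", "alt_count", "depth")

CONSEQUENCE_LEVELS <- c("synonymous", "missense", "nonsense", "deletion",
                        "insertion", "other")

#' Validate a somatic mutation table
#'
#' Checks the invariants every downstream stage assumes: non-empty
#' chromosome names, 1-based positions, `ref != alt`, `alt_count <= depth`,
#' and a unique (chrom, pos, ref, alt) key per record.
#'
#' @param tab Data frame with at least the columns
#'   `chrom, pos, ref, alt, gene, protein_pos, aa_ref, aa_alt, alt_count,
#'   depth` (plus optional `sample_id`, `transcript`, `consequence`).
#' @param sample_id Sample identifier used to fill a missing `sample_id`
#'   column.
#' @return The validated data frame, with `sample_id`, `transcript`,
#'   `consequence` and `key` columns filled in.
#' @export
validate_mutation_table <- function(tab, sample_id = NULL) {
  missing_cols <- setdiff(MUTATION_COLUMNS, names(tab))
  if (length(missing_cols) > 0)
    stop_format("mutation table is missing column(s): %s",
                paste(missing_cols, collapse = ", "))
  tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  if (is.null(tab$sample_id)) tab$sample_id <- sample_id %||% NA_character_
  if (is.null(tab$transcript)) tab$transcript <- NA_character_
  tab$pos <- as.integer(tab$pos)
  tab$alt_count <- as.integer(tab$alt_count)
  tab$depth <- as.integer(tab$depth)
  tab$protein_pos <- suppressWarnings(as.integer(tab$protein_pos))

  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows) > 0)
      stop_validation("%s in row(s) %s", what,
                      paste(utils::head(rows, 5), collapse = ", "))
  }
  bad(is.na(tab$chrom) | !nzchar(tab$chrom), "empty chromosome name")
  bad(is.na(tab$pos) | tab$pos < 1L, "position must be >= 1 (1-based)")
  bad(tab$ref == tab$alt, "ref equals alt")
  bad(is.na(tab$alt_count) | is.na(tab$depth) | tab$alt_count < 0L,
      "missing or negative read counts")
  bad(tab$alt_count > tab$depth, "alt_count exceeds depth")
  tab$key <- mutation_key(tab$chrom, tab$pos, tab$ref, tab$alt)
  # key uniqueness holds within a sample; recurrent hotspots may repeat a
  # key across samples in a combined cohort frame
  dup <- duplicated(paste(tab$sample_id, tab$key))
  if (any(dup))
    stop_validation("duplicate mutation key(s): %s",
                    paste(utils::head(unique(tab$key[dup]), 3), collapse = ", "))
  if (is.null(tab$consequence))
    tab$consequence <- infer_consequence_label(tab)
  tab
}

# Label a record from its fields alone (used when the input carries protein
# annotation but no consequence column). Length-changing alleles map to
# deletion/insertion; aa_alt "*" to nonsense; equal residues to synonymous.
#' @noRd
infer_consequence_label <- function(tab) {
  n_ref <- nchar(tab$ref)
  n_alt <- nchar(tab$alt)
  out <- rep("other", nrow(tab))
  out[n_ref > n_alt] <- "deletion"
  out[n_ref < n_alt] <- "insertion"
  snv <- n_ref == n_alt
  aa_ref <- as.character(tab$aa_ref)
  aa_alt <- as.character(tab$aa_alt)
  out[snv & !is.na(aa_alt) & aa_alt == "*"] <- "nonsense"
  out[snv & !is.na(aa_ref) & !is.na(aa_alt) & aa_ref == aa_alt &
        aa_alt != "*"] <- "synonymous"
  out[snv & !is.na(aa_ref) & !is.na(aa_alt) & aa_ref != aa_alt &
        nchar(aa_ref) == 1 & nchar(aa_alt) == 1 & aa_alt != "*"] <- "missense"
  out
}

#' Read a somatic mutation table
#'
#' Reads called somatic variants from a MAF-like TSV or from a single-sample
#' VCF. Coordinates are 1-based. The VCF dialect uses the sample column's
#' `AD`/`DP` FORMAT fields when present, else `AO`/`RO`; multi-allelic rows
#' are split into one record per alternate allele; protein-level annotation
#' is taken from the INFO keys `GENE`, `TRANSCRIPT`, `PPOS`, `AAREF`,
#' `AAALT`, `CSQ`.
#'
#' @param path File path.
#' @param format `"tsv"` or `"vcf"`.
#' @param sample_id Optional sample identifier (TSV without a `sample_id`
#'   column; ignored for VCF, which names the sample itself).
#' @return A validated mutation table (data frame).
#' @export
read_mutation_table <- function(path, format = c("tsv", "vcf"),
                                sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_format("no such file: %s", path)
  if (format == "tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
    return(validate_mutation_table(tab, sample_id = sample_id))
  }
  read_mutation_vcf(path)
}

#' @noRd
read_mutation_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- v@gt
  if (is.null(gt) || ncol(gt) != 2L)
    stop_format("VCF must be single-sample: %s", path)
  sample_id <- colnames(gt)[2]
  info_get <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))
    vapply(m, function(z) if (length(z) == 2) z[2] else NA_character_, "")
  }
  fmt_get <- function(i, key) {
    keys <- strsplit(gt[i, 1], ":", fixed = TRUE)[[1]]
    vals <- strsplit(gt[i, 2], ":", fixed = TRUE)[[1]]
    j <- match(key, keys)
    if (is.na(j) || j > length(vals)) NA_character_ else vals[j]
  }
  recs <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    ad <- fmt_get(i, "AD")
    dp <- fmt_get(i, "DP")
    ao <- fmt_get(i, "AO")
    ro <- fmt_get(i, "RO")
    if (!is.na(ad)) {
      counts <- as.integer(strsplit(ad, ",", fixed = TRUE)[[1]])
      alt_counts <- counts[-1]
      depth <- if (!is.na(dp)) as.integer(dp) else sum(counts)
    } else if (!is.na(ao)) {
      alt_counts <- as.integer(strsplit(ao, ",", fixed = TRUE)[[1]])
      depth <- if (!is.na(dp)) as.integer(dp)
               else as.integer(ro) + sum(alt_counts)
    } else {
      stop_format("VCF record %d carries neither AD/DP nor AO/RO", i)
    }
    if (length(alt_counts) != length(alts))
      stop_format("VCF record %d: %d alt alleles but %d alt counts",
                  i, length(alts), length(alt_counts))
    info <- fix$INFO[i]
    for (j in seq_along(alts)) {
      recs[[length(recs) + 1L]] <- data.frame(
        sample_id = sample_id, chrom = fix$CHROM[i],
        pos = as.integer(fix$POS[i]), ref = fix$REF[i], alt = alts[j],
        gene = info_get(info, "GENE"),
        transcript = info_get(info, "TRANSCRIPT"),
        protein_pos = suppressWarnings(as.integer(info_get(info, "PPOS"))),
        aa_ref = info_get(info, "AAREF"), aa_alt = info_get(info, "AAALT"),
        consequence = info_get(info, "CSQ"),
        alt_count = alt_counts[j], depth = depth,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, recs)
  if (all(is.na(tab$consequence))) tab$consequence <- NULL
  validate_mutation_table(tab)
}

#' Write a somatic mutation table
#'
#' @param tab Validated mutation table.
#' @param path Output path.
#' @param format `"tsv"` or `"vcf"` (single-sample dialect documented in
#'   [read_mutation_table()]).
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(tab, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  tab <- validate_mutation_table(tab)
  if (format == "tsv") {
    cols <- c("sample_id", MUTATION_COLUMNS, "transcript", "consequence")
    utils::write.table(tab[, cols], path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  sample_id <- tab$sample_id[1] %||% "SAMPLE"
  hdr <- c("##fileformat=VCFv4.2",
           "##source=neoepitree",
           "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
           "##INFO=<ID=TRANSCRIPT,Number=1,Type=String,Description=\"Transcript\">",
           "##INFO=<ID=PPOS,Number=1,Type=Integer,Description=\"Protein position (1-based)\">",
           "##INFO=<ID=AAREF,Number=1,Type=String,Description=\"Reference residue\">",
           "##INFO=<ID=AAALT,Number=1,Type=String,Description=\"Alternate residue\">",
           "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence class\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample_id, sep = "\t"))
  info_field <- function(key, val) {
    ifelse(is.na(val), NA_character_, paste0(key, "=", val))
  }
  info <- apply(cbind(info_field("GENE", tab$gene),
                      info_field("TRANSCRIPT", tab$transcript),
                      info_field("PPOS", tab$protein_pos),
                      info_field("AAREF", tab$aa_ref),
                      info_field("AAALT", tab$aa_alt),
                      info_field("CSQ", tab$consequence)), 1,
                function(z) {
                  z <- z[!is.na(z)]
                  if (length(z) == 0) "." else paste(z, collapse = ";")
                })
  body <- paste(tab$chrom, tab$pos, ".", tab$ref, tab$alt, ".", "PASS",
                info, "GT:AD:DP",
                paste0("0/1:", tab$depth - tab$alt_count, ",", tab$alt_count,
                       ":", tab$depth),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Tab-separated lines: set name, description, then member gene symbols.
#' Duplicate symbols within a line are deduplicated. Gene symbols are
#' compared case-sensitively after whitespace trimming; no alias resolution
#' is attempted.
#'
#' @param path GMT file path.
#' @param universe Optional gene universe (character). Defaults to the union
#'   of all pathway genes; pathway genes absent from a supplied universe are
#'   flagged in the `missing` field.
#' @return A `pathway_collection` (see [pathway_collection()]).
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) stop_format("no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop_format("no pathways in %s", path)
  pathways <- list()
  for (i in seq_along(lines)) {
    fields <- trimws(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (length(fields) < 3)
      stop_format("GMT line %d has %d field(s); need name, description, genes",
                  i, length(fields))
    name <- fields[1]
    if (name %in% names(pathways))
      stop_format("GMT line %d: duplicate pathway name '%s'", i, name)
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) stop_format("GMT line %d: pathway '%s' is empty",
                                        i, name)
    pathways[[name]] <- genes
  }
  pathway_collection(pathways, universe = universe)
}

#' Write a GMT gene-set file
#'
#' @param collection A `pathway_collection` or a named list of gene vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  pw <- if (inherits(collection, "pathway_collection")) collection$pathways
        else collection
  lines <- vapply(names(pw), function(nm) {
    paste(c(nm, "na", pw[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased and whitespace-stripped; the sequence name is
#' the first whitespace-delimited token of the header (PaVE-style headers
#' therefore keep their accession). Duplicate names are an error.
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_format("no such file: %s", path)
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(gsub("[[:space:]]", "", as.character(set)))
  names(seqs) <- vapply(strsplit(names(set), "[[:space:]]+"), `[[`, "", 1)
  if (anyDuplicated(names(seqs)))
    stop_format("duplicate FASTA header: %s",
                names(seqs)[duplicated(names(seqs))][1])
  seqs
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# ---- read pairs -----------------------------------------------------------

#' Infer the target class of a reference name
#'
#' `"*"` is unmapped; names matching `hpv_pattern` are HPV; everything else
#' is host.
#' @param reference Character vector of reference names.
#' @param hpv_pattern Regular expression identifying HPV references.
#' @return Character vector in `{host, hpv, unmapped}`.
#' @export
infer_target_class <- function(reference, hpv_pattern = "^HPV") {
  out <- ifelse(reference == "*", "unmapped",
                ifelse(grepl(hpv_pattern, reference), "hpv", "host"))
  out
}

#' @noRd
make_read_pair_frame <- function(pair_id, ref1, pos1, frac1, ref2, pos2,
                                 frac2, hpv_pattern = "^HPV") {
  df <- data.frame(pair_id = as.character(pair_id),
                   class1 = infer_target_class(ref1, hpv_pattern),
                   ref1 = ref1, pos1 = as.integer(pos1),
                   frac1 = as.numeric(frac1),
                   class2 = infer_target_class(ref2, hpv_pattern),
                   ref2 = ref2, pos2 = as.integer(pos2),
                   frac2 = as.numeric(frac2),
                   stringsAsFactors = FALSE)
  bad1 <- (df$class1 == "unmapped") != (df$frac1 == 0)
  bad2 <- (df$class2 == "unmapped") != (df$frac2 == 0)
  if (any(bad1 | bad2))
    stop_validation("matched_fraction must be 0 exactly for unmapped ends (pair %s)",
                    df$pair_id[which(bad1 | bad2)[1]])
  df
}

#' Read mapped read pairs
#'
#' Two encodings of the same records are accepted: a 7-column TSV
#' (`pair_id, ref1, pos1, frac1, ref2, pos2, frac2`) and a minimal SAM
#' subset using only QNAME, FLAG, RNAME, POS plus an optional `XF:f:` tag
#' carrying the matched fraction (default 1 for mapped ends; CIGAR and
#' qualities are ignored). Ends are paired by read name; a read name with
#' more than two records is an error, unmatched singletons are dropped with
#' a warning and reported in the `"unpaired"` attribute.
#'
#' @param path Input path.
#' @param format `"tsv"` or `"sam_min"`.
#' @param hpv_pattern Regex distinguishing HPV reference names from host.
#' @return Data frame with columns `pair_id, class1, ref1, pos1, frac1,
#'   class2, ref2, pos2, frac2`, one row per pair.
#' @export
read_read_pairs <- function(path, format = c("tsv", "sam_min"),
                            hpv_pattern = "^HPV") {
  format <- match.arg(format)
  if (!file.exists(path)) stop_format("no such file: %s", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("pair_id", "ref1", "pos1", "frac1", "ref2", "pos2", "frac2")
    if (!all(need %in% names(df)))
      stop_format("read-pair TSV needs columns: %s", paste(need, collapse = ", "))
    return(make_read_pair_frame(df$pair_id, df$ref1, df$pos1, df$frac1,
                                df$ref2, df$pos2, df$frac2, hpv_pattern))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 4)
  if (length(short) > 0)
    stop_format("SAM line %d has fewer than 4 fields", short[1])
  qname <- vapply(fields, `[[`, "", 1)
  rname <- vapply(fields, `[[`, "", 3)
  pos <- as.integer(vapply(fields, `[[`, "", 4))
  frac <- vapply(fields, function(z) {
    tag <- grep("^XF:f:", z, value = TRUE)
    if (length(tag) > 0) as.numeric(sub("^XF:f:", "", tag[1])) else NA_real_
  }, numeric(1))
  frac[is.na(frac)] <- ifelse(rname[is.na(frac)] == "*", 0, 1)
  counts <- table(qname)
  if (any(counts > 2))
    stop_format("read name '%s' occurs %d times; pairs must have exactly two ends",
                names(counts)[counts > 2][1], max(counts))
  unpaired <- names(counts)[counts == 1]
  if (length(unpaired) > 0)
    warning(sprintf("%d unmatched mate(s) dropped (e.g. %s)",
                    length(unpaired), unpaired[1]))
  keep <- qname %in% names(counts)[counts == 2]
  qn <- qname[keep]; rn <- rname[keep]; ps <- pos[keep]; fr <- frac[keep]
  first <- !duplicated(qn)
  o1 <- which(first); names(o1) <- qn[first]
  o2 <- which(!first); names(o2) <- qn[!first]
  ids <- sort(unique(qn))
  df <- make_read_pair_frame(ids, rn[o1[ids]], ps[o1[ids]], fr[o1[ids]],
                             rn[o2[ids]], ps[o2[ids]], fr[o2[ids]],
                             hpv_pattern)
  attr(df, "unpaired") <- unpaired
  df
}

#' Write read pairs
#'
#' Inverse of [read_read_pairs()] for both encodings.
#' @param pairs Data frame as returned by [read_read_pairs()].
#' @param path Output path.
#' @param format `"tsv"` or `"sam_min"`.
#' @return `path`, invisibly.
#' @export
write_read_pairs <- function(pairs, path, format = c("tsv", "sam_min")) {
  format <- match.arg(format)
  if (format == "tsv") {
    cols <- c("pair_id", "ref1", "pos1", "frac1", "ref2", "pos2", "frac2")
    utils::write.table(pairs[, cols], path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  flag <- function(mate1, unmapped) 1L + ifelse(mate1, 64L, 128L) +
    ifelse(unmapped, 4L, 0L)
  l1 <- paste(pairs$pair_id, flag(TRUE, pairs$ref1 == "*"), pairs$ref1,
              ifelse(pairs$ref1 == "*", 0L, pairs$pos1),
              paste0("XF:f:", pairs$frac1), sep = "\t")
  l2 <- paste(pairs$pair_id, flag(FALSE, pairs$ref2 == "*"), pairs$ref2,
              ifelse(pairs$ref2 == "*", 0L, pairs$pos2),
              paste0("XF:f:", pairs$frac2), sep = "\t")
  writeLines(c(rbind(l1, l2)), path)
  invisible(path)
}

# ---- clone-tree serialisation ---------------------------------------------

#' Serialise a clone tree
#'
#' Newick carries node names with cellular prevalences (CCF) as branch
#' lengths; JSON is lossless (see [read_tree_json()]); DOT reproduces the
#' usual clone-diagram styling classes (normal clones open, early clones
#' red, later clones blue).
#'
#' @param tree A `clone_tree` (see [clone_tree()]).
#' @param format `"newick"`, `"dot"` or `"json"`.
#' @param path Optional output file; the text is returned either way.
#' @return The serialised text (character scalar), invisibly when `path`
#'   is given.
#' @export
write_tree <- function(tree, format = c("newick", "dot", "json"),
                       path = NULL) {
  format <- match.arg(format)
  tree <- validate_clone_tree(tree)
  txt <- switch(format,
    newick = tree_to_newick(tree),
    dot = tree_to_dot(tree),
    json = tree_to_json(tree))
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @noRd
tree_children <- function(tree, node) {
  sort(names(tree$parent)[tree$parent == node])
}

#' @noRd
tree_to_newick <- function(tree) {
  recurse <- function(node) {
    kids <- tree_children(tree, node)
    inner <- if (length(kids) > 0)
      paste0("(", paste(vapply(kids, recurse, ""), collapse = ","), ")")
    else ""
    if (node == tree$root) paste0(inner, node)
    else paste0(inner, node, ":", format(tree$ccf[[node]], digits = 6))
  }
  paste0(recurse(tree$root), ";")
}

#' @noRd
tree_to_dot <- function(tree) {
  style <- function(node) {
    lab <- tree$label[[node]]
    cls <- switch(lab, normal = "normal", ancestor = "early", "late")
    col <- switch(cls, normal = "white", early = "red", late = "blue")
    sprintf("  \"%s\" [class=%s, shape=circle, style=filled, fillcolor=%s, label=\"%s\\nCCF=%.2f\"];",
            node, cls, col, node, tree$ccf[[node]])
  }
  nodes <- vapply(tree$nodes, style, "")
  edges <- vapply(names(tree$parent), function(ch) {
    sprintf("  \"%s\" -> \"%s\";", tree$parent[[ch]], ch)
  }, "")
  paste(c("digraph clone_tree {", nodes, edges, "}"), collapse = "\n")
}

#' @noRd
tree_to_json <- function(tree) {
  obj <- list(root = tree$root,
              nodes = tree$nodes,
              parent = as.list(tree$parent),
              ccf = as.list(tree$ccf),
              label = as.list(tree$label),
              n_mutations = if (is.null(tree$n_mutations)) NULL
                            else as.list(tree$n_mutations),
              loglik = if (is.na(tree$loglik)) NULL else tree$loglik)
  as.character(jsonlite::toJSON(obj[!vapply(obj, is.null, TRUE)],
                                auto_unbox = TRUE, digits = NA))
}

#' Read a clone tree from its JSON serialisation
#'
#' @param text JSON text, or a path to a file containing it.
#' @return A `clone_tree`.
#' @export
read_tree_json <- function(text) {
  if (length(text) == 1 && !startsWith(trimws(text), "{") && file.exists(text))
    text <- paste(readLines(text), collapse = "\n")
  obj <- jsonlite::fromJSON(text, simplifyVector = TRUE)
  clone_tree(parent = unlist(obj$parent),
             ccf = unlist(obj$ccf),
             root = obj$root,
             label = if (!is.null(obj$label)) unlist(obj$label) else NULL,
             n_mutations = if (!is.null(obj$n_mutations))
               unlist(obj$n_mutations) else NULL,
             loglik = obj$loglik %||% NA_real_)
}
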