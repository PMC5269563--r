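# Synthetic-cohort generator. Emulates the statistical structure the
# analysis assumes: a 23-tumor cohort averaging ~117 somatic mutations per
# tumor at ~181X depth, 1-3 subclones per tumor with linear or branching
# topology under the prevalence sum rule, a consequence mix matching the
# cohort's printed class totals, ~55% of missense mutations immunogenic
# under the deterministic mock affinity predictor, population-panel
# contaminants to exercise germline filtering, and HPV read mixtures
# (synthetic stand-in genomes named after the real genotypes) with rare
# host/HPV chimeric pairs. Ground truth (trees, clone assignments,
# immunogenic flags, injected panel variants, chimeric pair ids) is
# retained for recovery tests. All randomness flows through one run seed;
# per-tumor substreams are derived from (seed, tumor index) so cohorts are
# reproducible regardless of evaluation order. Copy number is not
# simulated: the diploid heterozygous model is used throughout.

#' Simulation configuration
#'
#' Defaults follow the cohort the pipeline is designed around: 23 tumors,
#' 117 expected mutations per tumor, 181X expected depth, 1-3 subclones,
#' 55% of missense mutations immunogenic.
#'
#' @param n_tumors Number of tumors.
#' @param mutations_per_tumor_mean Poisson mean mutation count per tumor.
#' @param depth_mean Poisson mean sequencing depth (floored at 10).
#' @param purity Tumor purity in (0, 1].
#' @param clone_count_range Inclusive range of subclone counts per tumor.
#' @param ccf_separation_min Minimum pairwise CCF gap between subclones.
#' @param immunogenic_fraction Designed fraction of missense mutations
#'   passing the 50/500 nM rule under the mock predictor.
#' @param n_pathways,pathway_size_range Gene-set collection shape.
#' @param n_genes Size of the synthetic gene universe.
#' @param panel_contamination Fraction of extra population variants (MAF
#'   above threshold) injected per tumor to exercise filtering.
#' @param maf_threshold Population-panel removal threshold.
#' @param hpv_pairs_per_tumor Read pairs simulated per tumor.
#' @param hpv_chimeric_pairs Host/HPV chimeric pairs per HPV-positive
#'   tumor.
#' @param hpv_positive_fraction Fraction of tumors carrying chimeric
#'   pairs.
#' @param hpv_genotype_weights Sampling weights of the HPV-16/18/33
#'   genotypes across tumors.
#' @param read_length,hpv_substitution_rate Read simulation parameters.
#' @param alleles HLA alleles scored by the epitope caller.
#' @param flank,window_length Peptide extraction parameters.
#' @param seed Run seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_tumors = 23,
                       mutations_per_tumor_mean = 117,
                       depth_mean = 181,
                       purity = 1,
                       clone_count_range = c(1, 3),
                       ccf_separation_min = 0.15,
                       immunogenic_fraction = 0.55,
                       n_pathways = 20,
                       pathway_size_range = c(10, 60),
                       n_genes = 1200,
                       panel_contamination = 0.1,
                       maf_threshold = 0.1,
                       hpv_pairs_per_tumor = 60,
                       hpv_chimeric_pairs = 5,
                       hpv_positive_fraction = 17 / 23,
                       hpv_genotype_weights = c(HPV16 = 18, HPV18 = 3,
                                                HPV33 = 1),
                       read_length = 100,
                       hpv_substitution_rate = 0.01,
                       alleles = c("HLA-A0201", "HLA-B0702", "HLA-C0701"),
                       flank = 8,
                       window_length = 9,
                       seed = 1) {
  cfg <- as.list(environment())
  if (any(vapply(cfg[c("n_tumors", "mutations_per_tumor_mean", "depth_mean",
                       "n_pathways", "n_genes", "hpv_pairs_per_tumor",
                       "hpv_chimeric_pairs")], function(x) x < 0, TRUE)))
    stop_validation("counts must be >= 0")
  if (purity <= 0 || purity > 1) stop_validation("purity must be in (0, 1]")
  if (ccf_separation_min <= 0 || ccf_separation_min >= 1)
    stop_validation("ccf_separation_min must be in (0, 1)")
  if (immunogenic_fraction < 0 || immunogenic_fraction > 1)
    stop_validation("immunogenic_fraction must be in [0, 1]")
  structure(cfg, class = "sim_config")
}

#' Simulate a clone tree
#'
#' The founding (top) clone is clonal (CCF 1); remaining subclone CCFs are
#' drawn with pairwise gaps of at least `ccf_separation_min`, and each
#' clone attaches to a parent with enough spare prevalence, so the
#' prevalence sum rule holds exactly by construction. Both linear and
#' branching topologies arise.
#'
#' @param n_clones Number of subclones (1-6).
#' @param ccf_separation_min Minimum pairwise CCF gap.
#' @param seed Optional RNG seed.
#' @return A `clone_tree` rooted at the normal node.
#' @export
simulate_clone_tree <- function(n_clones, ccf_separation_min = 0.15,
                                seed = NULL) {
  if (n_clones < 1 || n_clones > 6)
    stop_validation("n_clones must be in 1..6")
  ccf_min <- 0.1
  if (n_clones > 1 &&
      (n_clones - 1) * ccf_separation_min > (1 - ccf_separation_min) - ccf_min)
    stop_validation("separation %.2f infeasible for %d clones",
                    ccf_separation_min, n_clones)
  with_seed(seed, {
    for (try in 1:1000) {
      ccf <- 1
      if (n_clones > 1) {
        rest <- sort(stats::runif(n_clones - 1, ccf_min,
                                  1 - ccf_separation_min),
                     decreasing = TRUE)
        if (length(rest) > 1 && min(-diff(rest)) < ccf_separation_min) next
        ccf <- c(1, rest)
      }
      ids <- paste0("C", seq_len(n_clones))
      names(ccf) <- ids
      parent <- character(n_clones)
      names(parent) <- ids
      used <- stats::setNames(numeric(n_clones + 1), c("Normal", ids))
      cap <- c(Normal = 1, ccf)
      ok <- TRUE
      for (i in seq_len(n_clones)) {
        avail <- names(cap)[seq_len(i)][cap[seq_len(i)] - used[seq_len(i)] >=
                                          ccf[i] - 1e-12]
        if (length(avail) == 0) { ok <- FALSE; break }
        pick <- if (length(avail) == 1) avail else sample(avail, 1)
        parent[i] <- pick
        used[pick] <- used[pick] + ccf[i]
      }
      if (ok) return(clone_tree(parent = parent, ccf = c(Normal = 1, ccf)))
    }
    stop_validation("failed to draw a feasible clone tree")
  })
}

# Cohort consequence-class mix: synonymous:nonsynonymous = 730:1934 with
# 18 deletions and 9 insertions per 2691 mutations; missense is 72% of
# nonsynonymous substitutions.
#' @noRd
consequence_probs <- function() {
  base <- c(synonymous = 730, nonsynonymous = 1934, deletion = 18,
            insertion = 9) / 2691
  c(synonymous = unname(base["synonymous"]),
    missense = unname(base["nonsynonymous"]) * 0.72,
    nonsense = unname(base["nonsynonymous"]) * 0.28,
    deletion = unname(base["deletion"]),
    insertion = unname(base["insertion"]))
}

#' Simulate a tumor's mutation table from a clone tree
#'
#' Every clone receives at least one marker mutation; the rest are split
#' uniformly. Depth is Poisson (floored at 10) and the alt count is
#' Binomial(depth, purity * CCF / 2) under the diploid heterozygous model,
#' floored at one supporting read. Consequence classes follow the cohort
#' mix (see package docs).
#'
#' @param tree A `clone_tree`.
#' @param n_mutations Number of mutations (>= number of clones).
#' @param depth_mean Poisson depth mean.
#' @param purity Tumor purity.
#' @param sample_id Sample name.
#' @param gene_pool Gene symbols to draw from.
#' @param gene_weights Optional sampling weights over `gene_pool`.
#' @param seed Optional RNG seed.
#' @return A validated mutation table; the true clone of each mutation is
#'   in the `"clone_assignment"` attribute (named by mutation key).
#' @export
simulate_mutations <- function(tree, n_mutations, depth_mean = 181,
                               purity = 1, sample_id = "S1",
                               gene_pool = sprintf("G%04d", 1:1000),
                               gene_weights = NULL, seed = NULL) {
  clones <- setdiff(tree$nodes, tree$root)
  K <- length(clones)
  if (n_mutations < K)
    stop_validation("n_mutations (%d) below clone count (%d): each clone needs a marker",
                    n_mutations, K)
  with_seed(seed, {
    assign_clone <- c(clones,
                      sample(clones, n_mutations - K, replace = TRUE))
    assign_clone <- sample(assign_clone)
    ccf <- tree$ccf[assign_clone]
    depth <- pmax(10L, stats::rpois(n_mutations, depth_mean))
    alt <- pmax(1L, stats::rbinom(n_mutations, depth, purity * ccf / 2))
    probs <- consequence_probs()
    consequence <- sample(names(probs), n_mutations, replace = TRUE,
                          prob = probs)
    chrom <- paste0("chr", sample(1:22, n_mutations, replace = TRUE))
    pos <- sample.int(5e7, n_mutations)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_mutations, replace = TRUE)
    alt_allele <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    for (i in which(consequence == "deletion")) {
      ext <- paste(sample(bases, sample(1:3, 1), replace = TRUE),
                   collapse = "")
      alt_allele[i] <- ref[i]
      ref[i] <- paste0(ref[i], ext)
    }
    for (i in which(consequence == "insertion")) {
      ext <- paste(sample(bases, sample(1:3, 1), replace = TRUE),
                   collapse = "")
      alt_allele[i] <- paste0(ref[i], ext)
    }
    gene <- sample(gene_pool, n_mutations, replace = TRUE,
                   prob = gene_weights)
    aa <- sample(AA_LETTERS, n_mutations, replace = TRUE)
    aa_alt <- vapply(aa, function(a) sample(setdiff(AA_LETTERS, a), 1), "")
    aa_ref <- aa
    aa_alt[consequence == "synonymous"] <- aa_ref[consequence == "synonymous"]
    aa_alt[consequence == "nonsense"] <- "*"
    is_indel <- consequence %in% c("deletion", "insertion")
    aa_ref[is_indel] <- NA_character_
    aa_alt[is_indel] <- NA_character_
    protein_pos <- sample.int(400, n_mutations, replace = TRUE)
    protein_pos[is_indel] <- NA_integer_
    tab <- data.frame(sample_id = sample_id, chrom = chrom, pos = pos,
                      ref = ref, alt = alt_allele, gene = gene,
                      transcript = NA_character_,
                      protein_pos = protein_pos, aa_ref = aa_ref,
                      aa_alt = aa_alt, consequence = consequence,
                      alt_count = alt, depth = depth,
                      stringsAsFactors = FALSE)
    tab <- validate_mutation_table(tab)
    attr(tab, "clone_assignment") <- stats::setNames(assign_clone, tab$key)
    tab
  })
}

#' Simulate a proteome consistent with a cohort's mutation annotations
#'
#' Emits one random protein per mutated gene and rewrites each SNV
#' record's `protein_pos`/`aa_ref` so the annotation matches the emitted
#' sequence (positions unique within a gene). A configurable fraction of
#' missense mutations is deliberately placed within `flank` residues of a
#' protein terminus so truncated (< 2*flank+1) peptides occur.
#'
#' @param tab Cohort mutation table.
#' @param flank Flank used downstream (controls terminus placement).
#' @param terminus_fraction Fraction of SNVs placed near a terminus.
#' @param seed Optional RNG seed.
#' @return List with `proteome` (named by gene) and `table` (updated).
#' @export
simulate_proteome <- function(tab, flank = 8, terminus_fraction = 0.05,
                              seed = NULL) {
  tab <- validate_mutation_table(tab)
  snv <- which(tab$consequence %in% c("missense", "synonymous", "nonsense"))
  genes <- sort(unique(tab$gene[snv]))
  with_seed(seed, {
    proteome <- stats::setNames(vector("character", length(genes)), genes)
    for (g in genes) {
      rows <- snv[tab$gene[snv] == g]
      L <- max(2 * flank + 1 + 20, sample(120:600, 1), na.rm = TRUE)
      seq_chars <- sample(AA_LETTERS, L, replace = TRUE)
      body <- (flank + 1):(L - flank)
      edge <- setdiff(1:L, body)
      n <- length(rows)
      near_term <- stats::runif(n) < terminus_fraction
      pool_b <- sample(body)
      pool_e <- sample(edge)
      pos <- integer(n)
      bi <- 1; ei <- 1
      for (j in seq_len(n)) {
        if (near_term[j] && ei <= length(pool_e)) {
          pos[j] <- pool_e[ei]; ei <- ei + 1
        } else {
          pos[j] <- pool_b[bi]; bi <- bi + 1
        }
      }
      tab$protein_pos[rows] <- pos
      tab$aa_ref[rows] <- seq_chars[pos]
      same <- tab$consequence[rows] == "synonymous"
      tab$aa_alt[rows][same] <- seq_chars[pos][same]
      mis <- tab$consequence[rows] == "missense"
      tab$aa_alt[rows][mis] <- vapply(seq_chars[pos][mis], function(a)
        sample(setdiff(AA_LETTERS, a), 1), "")
      proteome[[g]] <- paste(seq_chars, collapse = "")
    }
    list(proteome = proteome, table = validate_mutation_table(tab))
  })
}

#' Deterministic mock MHC-I affinity predictor
#'
#' A stable hash of (peptide, allele) is mapped to an IC50 in \[1, 50000\]
#' nM with region masses calibrated so that, over the default window-by-
#' allele grid, the designed fraction of mutant/wild-type peptide pairs
#' satisfies the 50/500 nM rule. Identical inputs always give identical
#' affinities; peptides with non-amino-acid letters are an error.
#'
#' @param peptide Character vector of peptides (length 8-11 residues).
#' @param allele Allele name (scalar).
#' @param immunogenic_fraction Designed fraction of missense mutations
#'   called immunogenic.
#' @param n_windows,n_alleles Grid size the calibration assumes (defaults
#'   match a 17-mer scanned with 9-mers over three alleles).
#' @return Numeric vector of affinities in nM (lower = stronger).
#' @export
mock_affinity_predictor <- function(peptide, allele,
                                    immunogenic_fraction = 0.55,
                                    n_windows = 9, n_alleles = 3) {
  if (any(nchar(peptide) < 8 | nchar(peptide) > 11))
    stop_validation("peptide length must be 8..11")
  chars <- unique(strsplit(paste(peptide, collapse = ""), "")[[1]])
  if (!all(chars %in% AA_LETTERS))
    stop_validation("peptide contains non-amino-acid letter(s): %s",
                    paste(setdiff(chars, AA_LETTERS), collapse = ""))
  f <- immunogenic_fraction
  q <- 1 - (1 - f)^(1 / (n_windows * n_alleles))
  a <- sqrt(q / 6)            # strong-binder mass (< 50 nM)
  b <- min(0.85, sqrt(6 * q)) # non-binder mass (> 500 nM)
  a <- q / b
  key <- paste(peptide, allele, sep = "|")
  u1 <- hash_unit(key, salt = 1)
  u2 <- hash_unit(key, salt = 2)
  ifelse(u1 < a, 1 + u2 * 49,
         ifelse(u1 < 1 - b, 50 + u2 * 450, 500 + u2 * 49500))
}

#' Build a mock predictor closure for a given design fraction
#'
#' @inheritParams mock_affinity_predictor
#' @param flank,window_length Determine the full-length window count the
#'   calibration assumes.
#' @param alleles Alleles the caller will scan.
#' @return A `function(peptide, allele)` suitable for
#'   [call_immunogenic()].
#' @export
make_mock_predictor <- function(immunogenic_fraction = 0.55, flank = 8,
                                window_length = 9,
                                alleles = c("HLA-A0201", "HLA-B0702",
                                            "HLA-C0701")) {
  n_windows <- (2 * flank + 1) - window_length + 1
  n_alleles <- length(alleles)
  function(peptide, allele)
    mock_affinity_predictor(peptide, allele,
                            immunogenic_fraction = immunogenic_fraction,
                            n_windows = n_windows, n_alleles = n_alleles)
}

#' Simulate synthetic host and HPV reference sequences
#'
#' Random sequences standing in for a host contig and HPV genomes (named
#' after the real genotypes; these are synthetic stand-ins, not the PaVE
#' references).
#'
#' @param host_length Host contig length.
#' @param hpv_lengths Named vector of genotype genome lengths.
#' @param seed Optional RNG seed.
#' @return List with `host` and `hpv` named character vectors.
#' @export
simulate_references <- function(host_length = 20000,
                                hpv_lengths = c(HPV16 = 7906, HPV18 = 7857,
                                                HPV33 = 7909),
                                seed = NULL) {
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    host <- stats::setNames(paste(sample(bases, host_length, replace = TRUE),
                                  collapse = ""), "chr_host")
    hpv <- vapply(hpv_lengths, function(L)
      paste(sample(bases, L, replace = TRUE), collapse = ""), "")
    list(host = host, hpv = hpv)
  })
}

#' @noRd
draw_read <- function(ref_seq, read_length, substitution_rate) {
  L <- nchar(ref_seq)
  start <- sample.int(L - read_length + 1L, 1)
  read <- substr(ref_seq, start, start + read_length - 1L)
  n_sub <- stats::rbinom(1, read_length, substitution_rate)
  if (n_sub > 0) {
    at <- sample.int(read_length, n_sub)
    chars <- strsplit(read, "")[[1]]
    for (i in at) chars[i] <- sample(setdiff(c("A", "C", "G", "T"),
                                             chars[i]), 1)
    read <- paste(chars, collapse = "")
  }
  if (stats::runif(1) < 0.5) read <- revcomp(read)
  read
}

#' Simulate read pairs with optional host/HPV chimeras
#'
#' Exactly `n_chimeric` pairs have one end copied from the host and one
#' from an HPV genotype; the remainder are pure host or pure HPV. Reads
#' carry independent substitution errors and random strand orientation.
#'
#' @param host_ref,hpv_refs Named reference vectors.
#' @param n_pairs Total pairs.
#' @param n_chimeric Chimeric pairs (<= n_pairs).
#' @param genotype HPV genotype used for viral ends (defaults to the
#'   first of `hpv_refs`).
#' @param hpv_fraction Fraction of non-chimeric pairs drawn from HPV.
#' @param read_length,substitution_rate Read model.
#' @param seed Optional RNG seed.
#' @return List with `pairs` (data frame `pair_id, read1, read2`),
#'   `chimeric_ids`, and `origins` (true source reference per end).
#' @export
simulate_hpv_reads <- function(host_ref, hpv_refs, n_pairs, n_chimeric,
                               genotype = names(hpv_refs)[1],
                               hpv_fraction = 0.2, read_length = 100,
                               substitution_rate = 0.01, seed = NULL) {
  if (n_chimeric > n_pairs)
    stop_validation("n_chimeric (%d) exceeds n_pairs (%d)", n_chimeric,
                    n_pairs)
  with_seed(seed, {
    ids <- sprintf("pair%05d", seq_len(n_pairs))
    type <- c(rep("chimeric", n_chimeric),
              ifelse(stats::runif(n_pairs - n_chimeric) < hpv_fraction,
                     "hpv", "host"))
    type <- sample(type)
    o1 <- o2 <- character(n_pairs)
    r1 <- r2 <- character(n_pairs)
    for (i in seq_len(n_pairs)) {
      src <- switch(type[i],
        chimeric = if (stats::runif(1) < 0.5)
          c(names(host_ref)[1], genotype) else c(genotype, names(host_ref)[1]),
        host = rep(names(host_ref)[1], 2),
        hpv = rep(genotype, 2))
      refs <- c(host_ref, hpv_refs)
      o1[i] <- src[1]; o2[i] <- src[2]
      r1[i] <- draw_read(refs[[src[1]]], read_length, substitution_rate)
      r2[i] <- draw_read(refs[[src[2]]], read_length, substitution_rate)
    }
    list(pairs = data.frame(pair_id = ids, read1 = r1, read2 = r2,
                            stringsAsFactors = FALSE),
         chimeric_ids = sort(ids[type == "chimeric"]),
         origins = data.frame(pair_id = ids, origin1 = o1, origin2 = o2,
                              stringsAsFactors = FALSE))
  })
}

#' Simulate a full cohort with ground truth
#'
#' Generates per-tumor clone trees, mutation tables (with population-panel
#' contaminants), a consistent proteome, a gene-set collection with two
#' designed enriched pathways, HPV read mixtures, and the ground truth
#' needed by recovery tests. When `dir` is given, every input file the
#' pipeline consumes is written there (TSV/VCF mutation tables, FASTA
#' proteome and references, GMT, panel TSV, per-tumor read FASTA, truth
#' JSON) — byte-identically for a given seed.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory.
#' @return List with `tumors` (per tumor: `table` including contaminants,
#'   `tree`, `hpv`), `proteome`, `pathways`, `panel`, `truth`, `config`.
#' @export
simulate_cohort <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- config$seed
  universe <- sprintf("G%04d", seq_len(config$n_genes))
  pathways <- with_seed(derive_seed(seed, 900001), {
    sizes <- sample(config$pathway_size_range[1]:config$pathway_size_range[2],
                    config$n_pathways, replace = TRUE)
    pw <- lapply(sizes, function(s) sample(universe, s))
    names(pw) <- sprintf("PW%02d", seq_len(config$n_pathways))
    pw
  })
  enriched <- names(pathways)[seq_len(min(2, length(pathways)))]
  gene_weights <- rep(1, length(universe))
  names(gene_weights) <- universe
  gene_weights[unique(unlist(pathways[enriched]))] <- 8
  collection <- pathway_collection(pathways, universe = universe)

  refs <- simulate_references(seed = derive_seed(seed, 900002))
  genotypes <- with_seed(derive_seed(seed, 900003), {
    sample(names(config$hpv_genotype_weights), config$n_tumors,
           replace = TRUE, prob = config$hpv_genotype_weights)
  })
  n_positive <- round(config$hpv_positive_fraction * config$n_tumors)

  sample_ids <- sprintf("S%d", seq_len(config$n_tumors))
  tumors <- vector("list", config$n_tumors)
  names(tumors) <- sample_ids
  panel_rows <- list()
  for (t in seq_len(config$n_tumors)) {
    sid <- sample_ids[t]
    tseed <- derive_seed(seed, t)
    tree <- simulate_clone_tree(
      with_seed(tseed, sample(config$clone_count_range[1]:
                                config$clone_count_range[2], 1)),
      config$ccf_separation_min, seed = derive_seed(tseed, 1))
    n_mut <- with_seed(derive_seed(tseed, 2),
                       max(length(tree$nodes) - 1, 3,
                           stats::rpois(1, config$mutations_per_tumor_mean)))
    tab <- simulate_mutations(tree, n_mut, depth_mean = config$depth_mean,
                              purity = config$purity, sample_id = sid,
                              gene_pool = universe,
                              gene_weights = gene_weights,
                              seed = derive_seed(tseed, 3))
    assignment <- attr(tab, "clone_assignment")
    # population-panel contaminants: germline het variants at MAF >= thr
    n_con <- round(config$panel_contamination * n_mut)
    con <- with_seed(derive_seed(tseed, 4), {
      if (n_con == 0) return(NULL)
      depth <- pmax(10L, stats::rpois(n_con, config$depth_mean))
      bases <- c("A", "C", "G", "T")
      ref <- sample(bases, n_con, replace = TRUE)
      data.frame(sample_id = sid,
                 chrom = paste0("chr", sample(1:22, n_con, replace = TRUE)),
                 pos = sample.int(1e6, n_con) + 5e7L,
                 ref = ref,
                 alt = vapply(ref, function(r) sample(setdiff(bases, r), 1), ""),
                 gene = sample(universe, n_con, replace = TRUE),
                 transcript = NA_character_,
                 protein_pos = sample.int(400, n_con, replace = TRUE),
                 aa_ref = sample(AA_LETTERS, n_con, replace = TRUE),
                 aa_alt = NA_character_,
                 consequence = NA_character_,
                 alt_count = pmax(1L, stats::rbinom(n_con, depth, 0.5)),
                 depth = depth, stringsAsFactors = FALSE)
    })
    if (!is.null(con)) {
      con$aa_alt <- with_seed(derive_seed(tseed, 5),
                              vapply(con$aa_ref, function(a)
                                sample(setdiff(AA_LETTERS, a), 1), ""))
      con$consequence <- "missense"
      con$maf <- with_seed(derive_seed(tseed, 6),
                           stats::runif(n_con, config$maf_threshold, 0.5))
      panel_rows[[sid]] <- con[, c("chrom", "pos", "ref", "alt", "maf")]
      cols <- c("sample_id", "chrom", "pos", "ref", "alt", "gene",
                "transcript", "protein_pos", "aa_ref", "aa_alt",
                "consequence", "alt_count", "depth")
      tab <- validate_mutation_table(rbind(tab[, cols], con[, cols]))
    }
    hpv_genotype <- genotypes[t]
    n_chim <- if (t <= n_positive) config$hpv_chimeric_pairs else 0L
    hpv <- simulate_hpv_reads(refs$host, refs$hpv,
                              n_pairs = config$hpv_pairs_per_tumor,
                              n_chimeric = n_chim,
                              genotype = hpv_genotype,
                              read_length = config$read_length,
                              substitution_rate = config$hpv_substitution_rate,
                              seed = derive_seed(tseed, 7))
    tumors[[sid]] <- list(table = tab, tree = tree,
                          assignment = assignment,
                          genotype = hpv_genotype, hpv = hpv)
  }

  injected <- lapply(panel_rows, function(df)
    mutation_key(df$chrom, df$pos, df$ref, df$alt))
  # a slice of true somatic mutations also sits in the panel *below* the
  # removal threshold, so filtering must keep them
  low_maf <- with_seed(derive_seed(seed, 900004), {
    all_keys <- unlist(lapply(names(tumors), function(sid) {
      keys <- tumors[[sid]]$table$key
      keys[!(keys %in% injected[[sid]])]
    }), use.names = FALSE)
    pick <- sample(all_keys, max(1, round(0.05 * length(all_keys))))
    parts <- strsplit(pick, ":", fixed = TRUE)
    data.frame(chrom = vapply(parts, `[[`, "", 1),
               pos = as.integer(vapply(parts, `[[`, "", 2)),
               ref = vapply(parts, `[[`, "", 3),
               alt = vapply(parts, `[[`, "", 4),
               maf = stats::runif(length(pick), 0,
                                  config$maf_threshold / 2),
               stringsAsFactors = FALSE)
  })
  panel_df <- unique(rbind(do.call(rbind, panel_rows), low_maf))
  panel <- population_panel(panel_df, name = "synthetic_panel")

  # consistent proteome over the whole cohort (contaminants included so
  # every annotated record matches a protein)
  combined <- do.call(rbind, lapply(tumors, function(tu) tu$table))
  prot <- simulate_proteome(combined, flank = config$flank,
                            seed = derive_seed(seed, 900005))
  combined <- prot$table
  for (sid in sample_ids) {
    tu_tab <- combined[combined$sample_id == sid, , drop = FALSE]
    rownames(tu_tab) <- NULL
    tumors[[sid]]$table <- tu_tab
  }

  # truth immunogenic flags: by construction, the epitope caller's output
  # on the true somatic mutations under the mock predictor
  predictor <- make_mock_predictor(config$immunogenic_fraction,
                                   flank = config$flank,
                                   window_length = config$window_length,
                                   alleles = config$alleles)
  truth_tumors <- lapply(sample_ids, function(sid) {
    tu <- tumors[[sid]]
    somatic <- tu$table[!(tu$table$key %in% injected[[sid]]), , drop = FALSE]
    calls <- call_epitopes(somatic, prot$proteome, config$alleles, predictor,
                           flank = config$flank,
                           window_length = config$window_length)
    list(tree = jsonlite::fromJSON(tree_to_json(tu$tree)),
         assignment = as.list(tu$assignment),
         immunogenic_keys = calls$key[calls$immunogenic],
         n_missense = nrow(calls),
         panel_injected = injected[[sid]] %||% character(),
         chimeric_pair_ids = tu$hpv$chimeric_ids,
         hpv_genotype = tu$genotype)
  })
  names(truth_tumors) <- sample_ids
  truth <- list(tumors = truth_tumors, enriched_pathways = enriched,
                seed = seed)

  out <- list(tumors = tumors, proteome = prot$proteome,
              pathways = collection, panel = panel, refs = refs,
              truth = truth, config = config)
  if (!is.null(dir)) write_cohort(out, dir)
  out
}

#' @noRd
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sid in names(cohort$tumors)) {
    tu <- cohort$tumors[[sid]]
    write_mutation_table(tu$table, file.path(dir, paste0(sid, ".mutations.tsv")),
                         "tsv")
    write_mutation_table(tu$table, file.path(dir, paste0(sid, ".mutations.vcf")),
                         "vcf")
    reads <- stats::setNames(
      c(rbind(tu$hpv$pairs$read1, tu$hpv$pairs$read2)),
      c(rbind(paste0(tu$hpv$pairs$pair_id, "/1"),
              paste0(tu$hpv$pairs$pair_id, "/2"))))
    write_fasta(reads, file.path(dir, paste0(sid, ".reads.fasta")))
  }
  write_fasta(cohort$proteome, file.path(dir, "proteome.fasta"))
  write_fasta(c(cohort$refs$host, cohort$refs$hpv),
              file.path(dir, "references.fasta"))
  write_gmt(cohort$pathways, file.path(dir, "pathways.gmt"))
  write_panel(cohort$panel, file.path(dir, "panel.tsv"))
  cfg <- cohort$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
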