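# Shared fixture builders: everything is generated in code at test time.

TEST_ALLELES <- c("HLA-A0201", "HLA-B0702", "HLA-C0701")

# Minimal hand-rolled mutation table; defaults give valid missense SNVs.
make_tab <- function(n = 3, sample_id = "S1", chrom = "chr1",
                     pos = seq_len(n), ref = "A", alt = "G",
                     gene = paste0("G", seq_len(n)), protein_pos = 10,
                     aa_ref = "K", aa_alt = "R", alt_count = 20, depth = 60,
                     consequence = NULL) {
  rl <- function(x) rep_len(x, n)
  df <- data.frame(sample_id = rl(sample_id), chrom = rl(chrom),
                   pos = rl(pos), ref = rl(ref), alt = rl(alt),
                   gene = rl(gene), protein_pos = rl(protein_pos),
                   aa_ref = rl(aa_ref), aa_alt = rl(aa_alt),
                   alt_count = rl(alt_count), depth = rl(depth),
                   stringsAsFactors = FALSE)
  if (!is.null(consequence)) df$consequence <- consequence
  df
}

# A one-clone tree with arbitrary subclone prevalence.
make_single_clone_tree <- function(ccf = 1) {
  clone_tree(parent = c(C1 = "Normal"), ccf = c(Normal = 1, C1 = ccf))
}

# Hand-built clone_clusters object with simulated read counts, for driving
# fit_tree() without going through EM.
make_clusters <- function(ccfs, n_per = 40, depth = 181, purity = 1,
                          seed = 42) {
  set.seed(seed)
  ids <- paste0("C", seq_along(ccfs))
  keys <- character(0)
  alt <- numeric(0)
  dep <- numeric(0)
  assignment <- character(0)
  clusters <- list()
  for (i in seq_along(ccfs)) {
    k <- paste0("m", i, "_", seq_len(n_per))
    d <- pmax(10, stats::rpois(n_per, depth))
    a <- pmax(1, stats::rbinom(n_per, d, purity * ccfs[i] / 2))
    keys <- c(keys, k)
    alt <- c(alt, a)
    dep <- c(dep, d)
    assignment <- c(assignment, stats::setNames(rep(ids[i], n_per), k))
    clusters[[i]] <- list(id = ids[i], ccf = ccfs[i], weight = 1 / length(ccfs),
                          members = k)
  }
  structure(list(clusters = clusters, assignment = assignment,
                 K = length(ccfs), loglik = NA_real_, bic = NA_real_,
                 purity = purity,
                 alt_count = stats::setNames(alt, keys),
                 depth = stats::setNames(dep, keys)),
            class = "clone_clusters")
}

# Independent scorer mirroring the documented tree-likelihood definition,
# used by brute-force tree-search oracles. Kept deliberately naive.
oracle_tree_score <- function(pv, clusters, epsilon = 0.05) {
  K <- clusters$K
  ccf <- vapply(clusters$clusters, `[[`, numeric(1), "ccf")
  for (node in 0:K) {
    kids <- which(pv == node)
    if (length(kids) == 0) next
    cap <- if (node == 0) 1 else ccf[node]
    if (sum(ccf[kids]) > cap + epsilon) return(NULL)
  }
  depth_of <- function(i) { d <- 0; cur <- i
    while (pv[cur] != 0) { cur <- pv[cur]; d <- d + 1 }; d }
  adj <- ccf
  for (i in order(vapply(seq_len(K), depth_of, 0)))
    adj[i] <- min(adj[i], if (pv[i] == 0) 1 else adj[pv[i]])
  for (node in c(0, order(vapply(seq_len(K), depth_of, 0)))) {
    kids <- which(pv == node)
    if (length(kids) == 0) next
    cap <- if (node == 0) 1 else adj[node]
    s <- sum(adj[kids])
    if (s > cap && s > 0) adj[kids] <- adj[kids] * cap / s
  }
  ids <- vapply(clusters$clusters, `[[`, "", "id")
  idx <- match(clusters$assignment, ids)
  sum(stats::dbinom(clusters$alt_count, clusters$depth,
                    pmax(clusters$purity * adj[idx] / 2, 1e-6), log = TRUE))
}

# All acyclic parent vectors over K clusters (0 = root), brute force.
oracle_parent_vectors <- function(K) {
  grid <- do.call(expand.grid, lapply(seq_len(K), function(i) setdiff(0:K, i)))
  keep <- apply(grid, 1, function(pv) {
    for (i in seq_len(K)) {
      cur <- i
      for (s in 0:K) { cur <- pv[cur]; if (cur == 0) break }
      if (cur != 0) return(FALSE)
    }
    TRUE
  })
  as.matrix(grid[keep, , drop = FALSE])
}
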