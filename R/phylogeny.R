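# Subclonal phylogeny reconstruction from variant read counts.
#
# The model: each somatic SNV sits in one subclone; under a diploid
# heterozygous model a mutation in a subclone with cancer cell fraction
# (CCF) phi in a tumor of purity rho has expected variant allele fraction
# rho * phi / 2, and the alt read count is Binomial(depth, rho * phi / 2).
# Clustering is a finite binomial mixture fitted by EM with the number of
# clones chosen by BIC; the clone tree is then the maximum-likelihood
# rooted tree over clusters satisfying the prevalence sum rule
# CCF(parent) >= sum CCF(children) - epsilon, found by exhaustive
# enumeration of parent vectors (tumors at this disease stage carry few
# subclones, so the search space is tiny and the optimum is exact).

#' Construct a clone tree
#'
#' A rooted tree of subclones. The root is a non-pathogenic "normal" node
#' with CCF 1 and no mutations; every other node is a mutation cluster with
#' a cellular prevalence.
#'
#' @param parent Named character vector: for every non-root node, the name
#'   of its parent.
#' @param ccf Named numeric vector of cellular prevalences over all nodes
#'   (the root must have CCF 1).
#' @param root Root node name.
#' @param label Optional named chronology labels in
#'   `{normal, ancestor, descendant, later}`; computed with
#'   [classify_clones()] when omitted.
#' @param n_mutations Optional named count of mutations per node.
#' @param loglik Optional log-likelihood of the tree.
#' @return An object of class `clone_tree`.
#' @export
clone_tree <- function(parent, ccf, root = "Normal", label = NULL,
                       n_mutations = NULL, loglik = NA_real_) {
  tree <- structure(list(root = root,
                         nodes = c(root, names(parent)),
                         parent = parent,
                         ccf = ccf,
                         label = label,
                         n_mutations = n_mutations,
                         loglik = loglik),
                    class = "clone_tree")
  tree <- validate_clone_tree(tree)
  if (is.null(tree$label)) tree <- classify_clones(tree)
  tree
}

#' @noRd
validate_clone_tree <- function(tree) {
  if (!is.list(tree) || is.null(tree$parent) || is.null(tree$ccf))
    stop_validation("not a clone tree")
  root <- tree$root %||% "Normal"
  nodes <- c(root, names(tree$parent))
  if (anyDuplicated(nodes))
    stop_validation("duplicate node names in clone tree")
  if (!all(tree$parent %in% nodes))
    stop_validation("parent map references unknown node(s): %s",
                    paste(setdiff(tree$parent, nodes), collapse = ", "))
  if (!all(nodes %in% names(tree$ccf)))
    stop_validation("missing CCF for node(s): %s",
                    paste(setdiff(nodes, names(tree$ccf)), collapse = ", "))
  if (any(tree$ccf < 0 | tree$ccf > 1 + 1e-9))
    stop_validation("CCF outside [0, 1]")
  if (abs(tree$ccf[[root]] - 1) > 1e-9)
    stop_validation("root CCF must be 1")
  # acyclicity: every node must reach the root
  for (node in names(tree$parent)) {
    seen <- character()
    cur <- node
    while (cur != root) {
      if (cur %in% seen) stop_validation("cycle in parent map at node %s", cur)
      seen <- c(seen, cur)
      cur <- tree$parent[[cur]]
    }
  }
  tree$nodes <- nodes
  tree$root <- root
  tree
}

#' Node depths of a clone tree
#' @noRd
tree_depths <- function(tree) {
  depth <- stats::setNames(integer(length(tree$nodes)), tree$nodes)
  for (node in names(tree$parent)) {
    d <- 0L
    cur <- node
    while (cur != tree$root) {
      d <- d + 1L
      cur <- tree$parent[[cur]]
    }
    depth[[node]] <- d
  }
  depth
}

#' Check the prevalence sum rule
#'
#' For every node, CCF(node) >= sum of children CCFs - epsilon.
#' @param tree A `clone_tree`.
#' @param epsilon Slack absorbing binomial sampling noise.
#' @return Logical scalar.
#' @export
satisfies_sum_rule <- function(tree, epsilon = 0) {
  for (node in tree$nodes) {
    kids <- names(tree$parent)[tree$parent == node]
    if (length(kids) > 0 &&
        sum(tree$ccf[kids]) > tree$ccf[[node]] + epsilon)
      return(FALSE)
  }
  TRUE
}

#' Label clones in chronological order
#'
#' Children of the normal root are ancestor subclones, their children
#' descendants, and anything deeper a later subclone.
#'
#' @param tree A `clone_tree`.
#' @return The tree with its `label` field filled in.
#' @export
classify_clones <- function(tree) {
  depth <- tree_depths(tree)
  lab <- ifelse(depth == 0L, "normal",
                ifelse(depth == 1L, "ancestor",
                       ifelse(depth == 2L, "descendant", "later")))
  tree$label <- stats::setNames(lab, names(depth))
  tree
}

#' Cancer cell fraction point estimate
#'
#' Diploid heterozygous transform: `CCF = min(1, 2 * (alt/depth) / purity)`.
#'
#' @param alt_count,depth Read counts (vectorised).
#' @param purity Tumor purity in (0, 1].
#' @return Numeric CCF estimates in \[0, 1\].
#' @export
estimate_ccf <- function(alt_count, depth, purity = 1) {
  if (any(depth <= 0)) stop_validation("depth must be positive")
  if (purity <= 0 || purity > 1) stop_validation("purity must be in (0, 1]")
  pmin(1, 2 * (alt_count / depth) / purity)
}

# ---- binomial mixture clustering ------------------------------------------

#' @noRd
binmix_em <- function(x, d, p0, purity, max_iter = 500, tol = 1e-8) {
  K <- length(p0)
  n <- length(x)
  p <- pmin(pmax(p0, 1e-4), purity / 2)
  pi_k <- rep(1 / K, K)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    lr <- vapply(seq_len(K), function(k)
      log(pi_k[k]) + stats::dbinom(x, d, p[k], log = TRUE), numeric(n))
    lr <- matrix(lr, nrow = n)
    mx <- apply(lr, 1, max)
    w <- exp(lr - mx)
    den <- rowSums(w)
    ll <- sum(mx + log(den))
    r <- w / den
    pi_k <- colMeans(r)
    p <- colSums(r * x) / pmax(colSums(r * d), 1e-12)
    p <- pmin(pmax(p, 1e-4), purity / 2)
    if (is.finite(ll) && ll - ll_old < tol && iter > 1) break
    ll_old <- ll
  }
  list(p = p, pi = pi_k, loglik = ll, resp = r)
}

#' Cluster mutations into clonal lineages
#'
#' Fits finite binomial mixtures to alt/depth read counts (success
#' probability `purity * CCF_k / 2` per component) for K = 1..`k_max` with
#' seeded EM restarts, selects K by BIC, hard-assigns each mutation to its
#' maximum-responsibility cluster, and relabels clusters `C1, C2, ...` in
#' decreasing CCF order.
#'
#' @param tab Mutation table with `alt_count` and `depth` (SNVs expected).
#' @param purity Tumor purity in (0, 1].
#' @param k_max Largest number of clusters considered.
#' @param n_restarts EM restarts per K; all restart seeds derive from
#'   `seed`.
#' @param seed Optional RNG seed for the restarts.
#' @return Object of class `clone_clusters`: list with `clusters` (per
#'   cluster: `id`, `ccf`, `weight`, `members`), `assignment` (named by
#'   mutation key), `K`, `loglik`, `bic` (vector over K), `purity`, and the
#'   per-mutation `alt_count`/`depth` used.
#' @export
cluster_mutations <- function(tab, purity = 1, k_max = 6, n_restarts = 10,
                              seed = NULL) {
  if (nrow(tab) < 1) stop_validation("need at least one mutation to cluster")
  if (purity <= 0 || purity > 1) stop_validation("purity must be in (0, 1]")
  x <- as.numeric(tab$alt_count)
  d <- as.numeric(tab$depth)
  keys <- tab$key %||% mutation_key(tab$chrom, tab$pos, tab$ref, tab$alt)
  n <- length(x)
  vaf <- x / d
  k_max <- min(k_max, n)
  fits <- vector("list", k_max)
  bic <- rep(NA_real_, k_max)
  with_seed(seed, {
    for (K in seq_len(k_max)) {
      best <- NULL
      for (r in seq_len(n_restarts)) {
        p0 <- if (r == 1)
          stats::quantile(vaf, probs = (seq_len(K) - 0.5) / K, names = FALSE)
        else sample(vaf, K, replace = TRUE) * stats::runif(K, 0.8, 1.2)
        fit <- binmix_em(x, d, p0, purity)
        if (is.null(best) || fit$loglik > best$loglik) best <- fit
      }
      fits[[K]] <- best
      bic[K] <- -2 * best$loglik + (2 * K - 1) * log(n)
    }
  })
  K <- which.min(bic)
  fit <- fits[[K]]
  hard <- max.col(fit$resp, ties.method = "first")
  # drop components that received no members, then order by CCF descending
  used <- sort(unique(hard))
  p_used <- fit$p[used]
  ord <- order(-p_used)
  relabel <- stats::setNames(seq_along(used)[order(ord)], used[ord])
  ids <- paste0("C", seq_along(used))
  assignment <- stats::setNames(ids[match(hard, used[ord])], keys)
  clusters <- lapply(seq_along(used), function(j) {
    k <- used[ord][j]
    members <- keys[hard == k]
    list(id = ids[j],
         ccf = min(1, 2 * fit$p[k] / purity),
         weight = fit$pi[k],
         members = members)
  })
  structure(list(clusters = clusters, assignment = assignment,
                 K = length(used), loglik = fit$loglik, bic = bic,
                 purity = purity,
                 alt_count = stats::setNames(x, keys),
                 depth = stats::setNames(d, keys)),
            class = "clone_clusters")
}

#' @export
print.clone_clusters <- function(x, ...) {
  cat(sprintf("Binomial mixture clustering: K = %d (BIC-selected), logLik = %.2f\n",
              x$K, x$loglik))
  for (cl in x$clusters)
    cat(sprintf("  %s: CCF %.3f, %d mutation(s)\n", cl$id, cl$ccf,
                length(cl$members)))
  invisible(x)
}

# ---- tree search ----------------------------------------------------------

#' @noRd
enumerate_parent_vectors <- function(K) {
  # parent index 0 = root; cluster i may attach to root or any other cluster
  choices <- lapply(seq_len(K), function(i) setdiff(0:K, i))
  grid <- do.call(expand.grid, choices)
  keep <- apply(grid, 1, function(pv) {
    for (i in seq_len(K)) {     # acyclicity: each node must reach the root
      cur <- i
      for (step in 0:K) {
        cur <- pv[cur]
        if (cur == 0) break
      }
      if (cur != 0) return(FALSE)
    }
    TRUE
  })
  grid <- grid[keep, , drop = FALSE]
  # lexicographic order of parent vectors fixes tie-breaking
  grid[do.call(order, as.list(grid)), , drop = FALSE]
}

# Adjust cluster CCFs top-down so the tree constraints hold exactly:
# each child is capped at its parent's adjusted CCF, and sibling sets
# exceeding the parent are rescaled proportionally.
#' @noRd
tree_adjust_ccf <- function(pv, ccf) {
  K <- length(ccf)
  adj <- ccf
  depth_order <- order(vapply(seq_len(K), function(i) {
    d <- 0; cur <- i
    while (pv[cur] != 0) { cur <- pv[cur]; d <- d + 1 }
    d
  }, numeric(1)))
  for (i in depth_order) {
    cap <- if (pv[i] == 0) 1 else adj[pv[i]]
    adj[i] <- min(adj[i], cap)
  }
  for (node in c(0, depth_order)) {
    kids <- which(pv == node)
    if (length(kids) == 0) next
    cap <- if (node == 0) 1 else adj[node]
    s <- sum(adj[kids])
    if (s > cap && s > 0) adj[kids] <- adj[kids] * cap / s
  }
  adj
}

#' Fit the maximum-likelihood clone tree over mutation clusters
#'
#' Enumerates every rooted tree over the clusters (normal node as root),
#' discards trees violating the prevalence sum rule beyond `epsilon`,
#' scores the remainder by the binomial likelihood of the observed read
#' counts under tree-consistent (constraint-projected) CCFs, and returns
#' the maximum; exact ties are broken by lexicographic parent-vector
#' order.
#'
#' @param clusters A `clone_clusters` object from [cluster_mutations()].
#' @param epsilon Sum-rule slack absorbing binomial sampling noise.
#' @return A `clone_tree` with chronology labels, per-clone mutation
#'   counts and the winning log-likelihood. Because a single sample cannot
#'   always distinguish topologies whose constraints are equally
#'   satisfied, every parent map tying the maximum likelihood is kept in
#'   the `ml_trees` field (the selected tree is its lexicographically
#'   first element).
#' @export
fit_tree <- function(clusters, epsilon = 0.05) {
  K <- clusters$K
  if (K > 6) stop_validation("exhaustive tree search supports at most 6 clusters")
  ccf <- vapply(clusters$clusters, `[[`, numeric(1), "ccf")
  ids <- vapply(clusters$clusters, `[[`, "", "id")
  sizes <- vapply(clusters$clusters, function(cl) length(cl$members), 0L)
  cl_index <- match(clusters$assignment, ids)
  x <- clusters$alt_count
  d <- clusters$depth
  purity <- clusters$purity
  grid <- enumerate_parent_vectors(K)
  best <- NULL
  scored <- list()
  violations <- character()
  for (r in seq_len(nrow(grid))) {
    pv <- as.integer(grid[r, ])
    feasible <- TRUE
    for (node in 0:K) {
      kids <- which(pv == node)
      if (length(kids) == 0) next
      cap <- if (node == 0) 1 else ccf[node]
      if (sum(ccf[kids]) > cap + epsilon) {
        feasible <- FALSE
        violations <- c(violations,
                        sprintf("parent %s: sum(children CCF) %.3f > %.3f + eps",
                                if (node == 0) "Normal" else ids[node],
                                sum(ccf[kids]), cap))
        break
      }
    }
    if (!feasible) next
    adj <- tree_adjust_ccf(pv, ccf)
    ll <- sum(stats::dbinom(x, d, pmax(purity * adj[cl_index] / 2, 1e-6),
                            log = TRUE))
    scored[[length(scored) + 1L]] <- list(pv = pv, ll = ll)
    if (is.null(best) || ll > best$ll + 1e-9) best <- list(pv = pv, ll = ll,
                                                           adj = adj)
  }
  if (is.null(best))
    stop_validation("no feasible tree under the prevalence sum rule; violations: %s",
                    paste(utils::head(unique(violations), 3), collapse = "; "))
  parent <- stats::setNames(c("Normal", ids)[best$pv + 1L], ids)
  tree <- clone_tree(parent = parent,
                     ccf = c(Normal = 1, stats::setNames(best$adj, ids)),
                     n_mutations = c(Normal = 0L, stats::setNames(sizes, ids)),
                     loglik = best$ll)
  tree$clusters <- clusters
  # a single tumor sample cannot always distinguish a chain from a sibling
  # split when the children's CCFs also fit side by side; every tree tying
  # the maximum likelihood is retained, the lexicographically first being
  # the selection above
  tree$ml_trees <- lapply(Filter(function(s) s$ll >= best$ll - 1e-6, scored),
                          function(s)
                            stats::setNames(c("Normal", ids)[s$pv + 1L], ids))
  tree
}

#' Fit a clone tree from a mutation table
#'
#' One-call interface: binomial-mixture clustering with BIC model
#' selection ([cluster_mutations()]), exhaustive constrained tree search
#' ([fit_tree()]) and chronological labelling ([classify_clones()]).
#'
#' @inheritParams cluster_mutations
#' @inheritParams fit_tree
#' @return A `clone_tree` (with the clustering kept in `$clusters`).
#' @export
fit_clone_tree <- function(tab, purity = 1, k_max = 6, epsilon = 0.05,
                           n_restarts = 10, seed = NULL) {
  clusters <- cluster_mutations(tab, purity = purity, k_max = k_max,
                                n_restarts = n_restarts, seed = seed)
  fit_tree(clusters, epsilon = epsilon)
}

#' @export
print.clone_tree <- function(x, ...) {
  cat(sprintf("Clone tree: %d subclone(s)%s\n", length(x$nodes) - 1L,
              if (is.na(x$loglik)) "" else sprintf(", logLik = %.2f", x$loglik)))
  recurse <- function(node, indent) {
    nm <- if (!is.null(x$n_mutations) && !is.na(x$n_mutations[node]))
      sprintf(" [%d mut]", x$n_mutations[[node]]) else ""
    cat(sprintf("%s%s (CCF %.2f, %s)%s\n", indent, node, x$ccf[[node]],
                x$label[[node]], nm))
    for (kid in tree_children(x, node)) recurse(kid, paste0(indent, "  "))
  }
  recurse(x$root, "")
  invisible(x)
}

#' @export
summary.clone_tree <- function(object, ...) {
  depth <- tree_depths(object)
  df <- data.frame(node = object$nodes,
                   parent = c(NA_character_,
                              object$parent[object$nodes[-1]]),
                   ccf = unname(object$ccf[object$nodes]),
                   depth = unname(depth[object$nodes]),
                   label = unname(object$label[object$nodes]),
                   n_mutations = if (is.null(object$n_mutations)) NA_integer_
                                 else unname(object$n_mutations[object$nodes]),
                   stringsAsFactors = FALSE)
  df$topology <- if (length(object$nodes) <= 2) "single"
                 else if (max(table(object$parent)) == 1) "linear"
                 else "branching"
  class(df) <- c("summary.clone_tree", "data.frame")
  df
}

#' Plot a clone tree
#'
#' Simple layered base-graphics rendering: normal root open, ancestor
#' clones red, descendant/later clones blue, arrows from parent to child.
#'
#' @param x A `clone_tree`.
#' @param ... Ignored.
#' @export
plot.clone_tree <- function(x, ...) {
  depth <- tree_depths(x)
  xpos <- stats::setNames(numeric(length(x$nodes)), x$nodes)
  leaf_counter <- 0
  recurse <- function(node) {
    kids <- tree_children(x, node)
    if (length(kids) == 0) {
      leaf_counter <<- leaf_counter + 1
      xpos[node] <<- leaf_counter
    } else {
      for (kid in kids) recurse(kid)
      xpos[node] <<- mean(xpos[kids])
    }
  }
  recurse(x$root)
  ypos <- -depth
  graphics::plot(NA, xlim = range(xpos) + c(-0.5, 0.5),
                 ylim = range(ypos) + c(-0.5, 0.5), axes = FALSE,
                 xlab = "", ylab = "", asp = NA)
  for (ch in names(x$parent))
    graphics::arrows(xpos[x$parent[[ch]]], ypos[x$parent[[ch]]] - 0.12,
                     xpos[ch], ypos[ch] + 0.15, length = 0.08)
  cols <- vapply(x$nodes, function(n)
    switch(x$label[[n]], normal = "white", ancestor = "red", "blue"), "")
  graphics::points(xpos, ypos[names(xpos)], pch = 21, bg = cols, cex = 3.5)
  graphics::text(xpos, ypos[names(xpos)] - 0.3,
                 sprintf("%s (%.2f)", names(xpos), x$ccf[names(xpos)]),
                 cex = 0.8)
  invisible(x)
}
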