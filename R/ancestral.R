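#' Maximum-likelihood ancestral states under Brownian motion
#'
#' For every internal node `v` the estimate is the Brownian-motion
#' root-state MLE of the tree re-rooted at `v`:
#' `a_v = (1' C_v^-1 x) / (1' C_v^-1 1)`, where `C_v[i, j]` is the shared
#' path length from `v` toward tips `i` and `j`. This equals the GLS
#' conditional mean of the node state given the tips (the classic
#' re-rooting construction). Deterministic; no smoothing or simulation.
#'
#' Shared path lengths relative to `v` are obtained from patristic
#' distances: `C_v[i, j] = (d(v, i) + d(v, j) - d(i, j)) / 2`.
#'
#' @param tree An ape `phylo` tree with branch lengths.
#' @param x Named trait vector matching the tip labels.
#' @return Named numeric vector of ancestral estimates for internal nodes,
#'   names `"<n+1>".."<n+Nnode>"` in ape node numbering (root first).
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1.5,D:1.5):0.5);")
#' ancestral_states_bm(tr, c(A = 1, B = 1.4, C = 3, D = 2.6))
ancestral_states_bm <- function(tree, x) {
  .check_tree(tree)
  x <- .align_trait(tree, x)
  n <- length(tree$tip.label)
  depths <- .node_depths(tree)
  C <- .mrca_depth_matrix(tree, depths)
  td <- depths[seq_len(n)]
  D <- outer(td, td, "+") - 2 * C          # tip-tip patristic distances
  topo <- .tree_topology(tree)
  nodes <- (n + 1L):(n + tree$Nnode)
  est <- numeric(length(nodes))
  names(est) <- as.character(nodes)
  for (idx in seq_along(nodes)) {
    v <- nodes[[idx]]
    # depth of mrca(v, tip) for every tip: walk the ancestor chain of v,
    # assigning each tip the first (deepest) ancestor containing it
    a_depth <- rep(NA_real_, n)
    node <- v
    while (node != 0L) {
      tips_in <- topo$member[node, ]
      new <- tips_in & is.na(a_depth)
      a_depth[new] <- depths[node]
      node <- topo$parent[node]
    }
    dv <- depths[v] + td - 2 * a_depth     # distance v -> each tip
    Cv <- (outer(dv, dv, "+") - D) / 2
    U <- tryCatch(chol(Cv), error = function(e) NULL)
    if (is.null(U))
      stop("singular covariance when re-rooting at node ", v,
           " (zero-length internal branch?)")
    ones <- rep(1, n)
    w1 <- backsolve(U, ones, transpose = TRUE)
    wx <- backsolve(U, x, transpose = TRUE)
    est[[idx]] <- sum(w1 * wx) / sum(w1 * w1)
  }
  est
}

#' Write ancestral-state estimates to TSV
#'
#' @param states Named vector from [ancestral_states_bm()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ancestral_tsv <- function(states, path) {
  utils::write.table(
    data.frame(node = names(states), estimate = unname(states)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
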