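# Tree bookkeeping on ape "phylo" objects. All quantities are derived
# directly from the edge matrix so the covariance builders do not depend on
# higher-level comparative packages.

.check_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(is.na(tree$edge.length))) stop("tree has NA branch lengths")
  if (any(tree$edge.length < 0)) stop("tree has negative branch lengths")
  if (anyDuplicated(tree$tip.label)) stop("tip labels must be unique")
  invisible(tree)
}

# Root-to-node depth for every node (tips 1..n, internals n+1..n+Nnode).
.node_depths <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  depth <- numeric(nn)
  ord <- tree
  if (is.null(attr(tree, "order")) || attr(tree, "order") != "cladewise")
    ord <- ape::reorder.phylo(tree, "cladewise")
  e <- ord$edge
  el <- ord$edge.length
  for (i in seq_len(nrow(e)))
    depth[e[i, 2L]] <- depth[e[i, 1L]] + el[i]
  depth
}

.tree_height <- function(tree, depths = .node_depths(tree)) {
  max(depths[seq_along(tree$tip.label)])
}

#' Is a tree ultrametric (within tolerance)?
#'
#' A tree is treated as ultrametric when the spread of root-to-tip depths
#' relative to tree height does not exceed `tol`. The Ornstein-Uhlenbeck
#' and early-burst covariances require this.
#'
#' @param tree An ape `phylo` tree with branch lengths.
#' @param tol Relative tolerance (default `1e-6`).
#' @return Logical scalar.
#' @export
is_ultrametric_tree <- function(tree, tol = 1e-6) {
  .check_tree(tree)
  d <- .node_depths(tree)[seq_along(tree$tip.label)]
  h <- max(d)
  if (h <= 0) return(TRUE)
  (max(d) - min(d)) / h <= tol
}

# Matrix of MRCA depths among tips (the Brownian-motion covariance up to
# sigma^2), built by postorder accumulation of subtree tip sets.
.mrca_depth_matrix <- function(tree, depths = .node_depths(tree)) {
  n <- length(tree$tip.label)
  C <- matrix(0, n, n)
  po <- ape::reorder.phylo(tree, "postorder")$edge
  tipsets <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) tipsets[[i]] <- i
  parents <- unique(po[, 1L])  # postorder: children before parents
  for (p in parents) {
    kids <- po[po[, 1L] == p, 2L]
    sets <- tipsets[kids]
    if (length(sets) > 1L) {
      for (a in seq_len(length(sets) - 1L)) {
        sa <- sets[[a]]
        rest <- unlist(sets[(a + 1L):length(sets)])
        C[sa, rest] <- depths[p]
        C[rest, sa] <- depths[p]
      }
    }
    tipsets[[p]] <- unlist(sets)
  }
  diag(C) <- depths[seq_len(n)]
  dimnames(C) <- list(tree$tip.label, tree$tip.label)
  C
}

# node -> tip subtree membership (logical matrix) and parent pointers.
.tree_topology <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  parent <- integer(nn)
  e <- tree$edge
  parent[e[, 2L]] <- e[, 1L]
  root <- setdiff(e[, 1L], e[, 2L])[[1L]]
  parent[root] <- 0L
  member <- matrix(FALSE, nn, n)
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(n)) member[i, i] <- TRUE
  for (p in unique(po[, 1L])) {
    kids <- po[po[, 1L] == p, 2L]
    member[p, ] <- Reduce(`|`, lapply(kids, function(k) member[k, ]))
  }
  list(parent = parent, root = root, member = member)
}

#' Prune a tree and trait table to their shared, fully observed species
#'
#' Drops species lacking complete data for the requested trait columns and
#' species absent from either the tree or the table, then reorders the
#' table to tip order. Branch lengths along removed paths are collapsed
#' correctly by [ape::drop.tip()] (degree-2 nodes merged, lengths summed).
#'
#' @param tree An ape `phylo` tree.
#' @param table Data frame with a species column and trait columns.
#' @param trait_cols Columns that must be non-missing; default all columns
#'   except `species_col`.
#' @param species_col Name of the species column.
#' @return List with elements `tree` and `table` (rows in tip order).
#' @export
prune_to_common <- function(tree, table, trait_cols = NULL,
                            species_col = "species") {
  .check_tree(tree)
  stopifnot(is.data.frame(table))
  if (!species_col %in% names(table))
    stop("table has no '", species_col, "' column")
  sp <- as.character(table[[species_col]])
  dup <- unique(sp[duplicated(sp)])
  if (length(dup) > 0L)
    stop("duplicate species rows in table: ", paste(dup, collapse = ", "))
  if (is.null(trait_cols)) trait_cols <- setdiff(names(table), species_col)
  missing_cols <- setdiff(trait_cols, names(table))
  if (length(missing_cols) > 0L)
    stop("table lacks trait columns: ", paste(missing_cols, collapse = ", "))
  complete <- stats::complete.cases(table[, trait_cols, drop = FALSE])
  shared <- intersect(tree$tip.label, sp[complete])
  if (length(shared) < 3L)
    stop("fewer than 3 shared species with complete trait data")
  pruned <- if (length(shared) == length(tree$tip.label)) tree
            else ape::drop.tip(tree, setdiff(tree$tip.label, shared))
  tab <- table[match(pruned$tip.label, sp), , drop = FALSE]
  rownames(tab) <- NULL
  list(tree = pruned, table = tab)
}
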