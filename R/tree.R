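#' Neighbor-joining tree with bootstrap support
#'
#' Builds an unrooted neighbor-joining tree on the identity distance
#' `1 - identity/100` derived from a multiple alignment, then bootstraps by
#' resampling alignment columns with replacement: each internal edge's
#' support is the fraction of replicate trees containing the same
#' bipartition of the leaf set.
#'
#' @param aln An `alignment` object (>= 3 sequences), or an
#'   `identity_matrix` (in which case `bootstrap_n` must be 0 since there
#'   are no columns to resample).
#' @param bootstrap_n Number of bootstrap replicates (0 disables).
#' @param seed Integer seed for column resampling.
#' @param denominator Identity convention passed to [identity_matrix()].
#' @return An `ape::phylo` tree; internal `node.label` holds bootstrap
#'   support in `[0, 1]` (empty label at the root node).
#' @export
nj_tree <- function(aln, bootstrap_n = 100, seed = 1,
                    denominator = "aligned") {
  if (inherits(aln, "identity_matrix")) {
    if (bootstrap_n > 0) {
      abort("bootstrap requires an alignment, not a precomputed matrix")
    }
    return(nj_from_identity(aln))
  }
  stopifnot(inherits(aln, "alignment"))
  if (length(aln$aligned) < 3L) abort("need at least 3 taxa for a tree")
  idm <- identity_matrix(aln, denominator = denominator)
  tree <- nj_from_identity(idm)
  if (bootstrap_n > 0) {
    m <- as.matrix(aln)
    L <- ncol(m)
    reps <- withr::with_seed(seed, {
      lapply(seq_len(bootstrap_n), function(b) {
        cols <- sample.int(L, L, replace = TRUE)
        sub <- aln
        sub$aligned <- setNames(
          apply(m[, cols, drop = FALSE], 1, paste, collapse = ""), aln$ids)
        nj_from_identity(identity_matrix(sub, denominator = denominator))
      })
    })
    counts <- ape::prop.clades(tree, reps, rooted = FALSE)
    counts[is.na(counts)] <- 0
    tree$node.label <- counts / bootstrap_n
  }
  tree
}

nj_from_identity <- function(idm) {
  d <- as.dist(1 - unclass(idm) / 100)
  ape::nj(d)
}

#' Test whether a set of leaves is monophyletic with support
#'
#' Convenience wrapper: monophyly via [ape::is.monophyletic()] and, when
#' the tree carries bootstrap labels, the support of the edge subtending
#' the group.
#'
#' @param tree A `phylo` tree from [nj_tree()].
#' @param tips Character vector of leaf labels.
#' @return A list with `monophyletic` (logical) and `support` (numeric or
#'   NA when unavailable).
#' @export
clade_support <- function(tree, tips) {
  mono <- ape::is.monophyletic(tree, tips)
  sup <- NA_real_
  if (mono && !is.null(tree$node.label)) {
    node <- ape::getMRCA(tree, tips)
    lab <- tree$node.label[node - length(tree$tip.label)]
    sup <- suppressWarnings(as.numeric(lab))
  }
  list(monophyletic = mono, support = sup)
}

#' Write a tree to newick with support values as internal labels
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
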