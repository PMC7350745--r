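#' Soft-threshold co-expression adjacency
#'
#' Standard weighted-network adjacency: `|cor|^beta` (unsigned) or
#' `((1 + cor)/2)^beta` (signed), with the diagonal set to zero so
#' downstream connectivity sums exclude self-edges. Genes must have
#' nonzero variance; use [filter_expression()] first.
#'
#' @param m Gene-by-sample numeric matrix (>= 4 samples).
#' @param beta Soft-threshold power (default 6, the customary unsigned
#'   default).
#' @param mode `"unsigned"` or `"signed"`.
#' @return Symmetric gene-by-gene matrix with zero diagonal.
#' @export
adjacency <- function(m, beta = 6, mode = c("unsigned", "signed")) {
  mode <- match.arg(mode)
  if (ncol(m) < 4) abort("need at least 4 samples")
  v <- apply(m, 1, sd)
  if (any(v == 0)) {
    abort(paste0("zero-variance gene reached adjacency: ",
                 rownames(m)[v == 0][1]))
  }
  cc <- cor(t(m))
  a <- if (mode == "unsigned") abs(cc)^beta else ((1 + cc) / 2)^beta
  diag(a) <- 0
  a
}

#' Remove low-information genes before network construction
#'
#' Keeps genes with nonzero variance and mean expression at or above
#' `min_mean` (on whatever scale `m` is in; the default suits
#' `log2(TPM + 1)` values).
#'
#' @param m Gene-by-sample matrix.
#' @param min_mean Mean-expression floor (default 0.1).
#' @return The filtered matrix.
#' @export
filter_expression <- function(m, min_mean = 0.1) {
  keep <- apply(m, 1, sd) > 0 & rowMeans(m) >= min_mean
  m[keep, , drop = FALSE]
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k_i = sum_u a_iu`, and `TOM_ii = 1`: the similarity of two genes'
#' network neighborhoods, the connectivity measure behind "most connected"
#' gene rankings.
#'
#' @param a Adjacency from [adjacency()] (symmetric, zero diagonal,
#'   entries in `[0, 1]`).
#' @return Symmetric matrix in `[0, 1]` with unit diagonal.
#' @export
tom <- function(a) {
  stopifnot(isSymmetric(unname(a)), all(diag(a) == 0),
            all(a >= 0), all(a <= 1))
  k <- rowSums(a)
  num <- a %*% a + a
  kmin <- outer(k, k, pmin)
  t <- num / (kmin + 1 - a)
  diag(t) <- 1
  dimnames(t) <- dimnames(a)
  t
}

#' Top-k most connected genes to a seed gene or clade
#'
#' For a single-gene seed, ranks all other genes by their TOM entry with
#' the seed. For a clade (id vector) seed, ranks genes by their mean TOM
#' to the clade members; members themselves compete for ranks when
#' `include_seed_members` (they are each other's strongest neighbors in a
#' co-regulated family). Ties break lexicographically by gene id, so
#' rankings are deterministic.
#'
#' @param t TOM from [tom()].
#' @param seed A gene id, or a character vector of clade member ids.
#' @param k Neighborhood size (default 100; larger than the matrix just
#'   returns the full ranking).
#' @param include_seed_members Whether clade members may occupy ranks.
#' @return Tibble (`gene`, `score`, `rank`).
#' @export
top_connected <- function(t, seed, k = 100, include_seed_members = TRUE) {
  genes <- rownames(t)
  if (!all(seed %in% genes)) {
    abort(paste0("seed gene absent from matrix: ",
                 setdiff(seed, genes)[1]))
  }
  if (length(seed) == 1L) {
    score <- t[seed, ]
    pool <- setdiff(genes, seed)
  } else {
    score <- rowMeans(t[, seed, drop = FALSE])
    pool <- if (include_seed_members) genes else setdiff(genes, seed)
  }
  score <- score[pool]
  ord <- order(-score, names(score))
  top <- head(ord, k)
  tibble(gene = names(score)[top], score = unname(score[top]),
         rank = seq_along(top))
}

#' Per-series clade neighborhoods
#'
#' Convenience wrapper running log2 transform, expression filtering,
#' adjacency, TOM and [top_connected()] for each series.
#'
#' @param series List of gene-by-sample matrices (raw scale).
#' @param seed Clade member ids (or one gene id).
#' @param k,beta,mode,include_seed_members See [top_connected()] and
#'   [adjacency()].
#' @param min_mean Expression floor for [filter_expression()].
#' @return Named list of neighborhood tibbles, one per series.
#' @export
series_neighborhoods <- function(series, seed, k = 100, beta = 6,
                                 mode = "unsigned",
                                 include_seed_members = TRUE,
                                 min_mean = 0.1) {
  lapply(series, function(m) {
    lm <- filter_expression(log2p1(m), min_mean = min_mean)
    t <- tom(adjacency(lm, beta = beta, mode = mode))
    top_connected(t, seed, k = k,
                  include_seed_members = include_seed_members)
  })
}

#' Cross-series consensus of clade neighborhoods
#'
#' Genes appearing in the top-k neighborhood of the clade in at least
#' `min_series` of the per-series analyses, with their series counts.
#' Clade (seed) members are excluded from the report: the interest is in
#' outside genes sharing the clade's expression pattern.
#'
#' @param neighborhoods List of tibbles from [series_neighborhoods()].
#' @param min_series Minimum number of series a gene must appear in.
#' @param exclude Gene ids (the clade) removed from the report.
#' @return Tibble (`gene`, `n_series`), sorted by descending count then
#'   id.
#' @export
consensus_neighborhood <- function(neighborhoods, min_series,
                                   exclude = character()) {
  if (length(neighborhoods) < 2) abort("need at least 2 series")
  counts <- purrr::map_dfr(neighborhoods, ~dplyr::distinct(.x,
                                                           .data$gene)) %>%
    dplyr::count(.data$gene, name = "n_series") %>%
    dplyr::filter(!.data$gene %in% exclude,
                  .data$n_series >= min_series) %>%
    dplyr::arrange(dplyr::desc(.data$n_series), .data$gene)
  counts
}
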