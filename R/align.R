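#' Substitution matrices used for alignment
#'
#' Protein alignments use BLOSUM62 (from Biostrings), restricted to the 20
#' standard residues plus X. DNA alignments use match +2 / mismatch -1,
#' with N scoring 0 against everything.
#'
#' @param type `"protein"` or `"dna"`.
#' @return A square numeric matrix with letter dimnames.
#' @export
default_submat <- function(type = c("protein", "dna")) {
  type <- match.arg(type)
  if (type == "protein") {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    ab <- ALPHABETS$protein
    e$BLOSUM62[ab, ab]
  } else {
    ab <- ALPHABETS$nucleotide
    s <- matrix(-1, 5, 5, dimnames = list(ab, ab))
    diag(s) <- 2
    s["N", ] <- 0
    s[, "N"] <- 0
    s
  }
}

default_gap <- function(type) {
  if (type == "protein") c(open = 10, extend = 1) else c(open = 10, extend = 0.5)
}

chars <- function(x) strsplit(x, "")[[1]]

#' Global pairwise alignment with affine gaps
#'
#' Optimal global alignment (Gotoh algorithm) of two sequences under a
#' substitution matrix and affine gap penalties; a gap of length L costs
#' `open + L * extend`. Percent identity is identical columns divided by
#' columns where at least one sequence is ungapped, times 100.
#'
#' @param a,b Sequences (single strings).
#' @param type `"protein"` or `"dna"`; sets the default scoring.
#' @param submat Substitution matrix; default per `type`.
#' @param gap_open,gap_extend Affine gap penalties.
#' @return A list with `score`, `identity` (percent), and `alignment`
#'   (character vector of the two aligned rows).
#' @export
pairwise_align <- function(a, b, type = c("protein", "dna"), submat = NULL,
                           gap_open = NULL, gap_extend = NULL) {
  type <- match.arg(type)
  if (!nzchar(a) || !nzchar(b)) abort("cannot align an empty sequence")
  if (is.null(submat)) submat <- default_submat(type)
  gp <- default_gap(type)
  if (is.null(gap_open)) gap_open <- gp[["open"]]
  if (is.null(gap_extend)) gap_extend <- gp[["extend"]]
  ca <- chars(a); cb <- chars(b)
  M <- submat[ca, cb, drop = FALSE]
  res <- gotoh_align_cpp(M, gap_open, gap_extend)
  row_a <- ifelse(res$path_a == 0L, "-", ca[pmax(res$path_a, 1L)])
  row_b <- ifelse(res$path_b == 0L, "-", cb[pmax(res$path_b, 1L)])
  ident <- 100 * sum(row_a == row_b & row_a != "-") / length(row_a)
  list(score = res$score, identity = ident,
       alignment = c(paste(row_a, collapse = ""), paste(row_b, collapse = "")))
}

new_alignment <- function(aligned, type) {
  stopifnot(length(unique(nchar(aligned))) == 1L)
  structure(list(ids = names(aligned), aligned = aligned, type = type),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("<alignment> %d sequences x %d columns (%s)\n",
              length(x$aligned), nchar(x$aligned[[1]]), x$type))
  invisible(x)
}

#' @export
as.matrix.alignment <- function(x, ...) {
  do.call(rbind, lapply(x$aligned, chars))
}

degap <- function(x) gsub("-", "", x, fixed = TRUE)

profile_of <- function(mat_rows, alphabet) {
  # column frequencies over the residue alphabet; gaps contribute zero
  # weight, so heavily gapped columns score low in profile products
  L <- ncol(mat_rows)
  P <- matrix(0, L, length(alphabet), dimnames = list(NULL, alphabet))
  n <- nrow(mat_rows)
  for (k in seq_along(alphabet)) {
    P[, k] <- colSums(mat_rows == alphabet[k]) / n
  }
  P
}

#' Progressive multiple sequence alignment
#'
#' Standard progressive alignment: all pairwise global alignments give an
#' identity matrix, a UPGMA guide tree is built on `1 - identity/100`, and
#' profiles are aligned profile-to-profile along the tree with the same
#' affine gap scheme (expected sum-of-pairs column scores).
#'
#' @param seqs Named character vector of >= 2 sequences.
#' @inheritParams pairwise_align
#' @return An `alignment` object.
#' @export
progressive_msa <- function(seqs, type = c("protein", "dna"), submat = NULL,
                            gap_open = NULL, gap_extend = NULL) {
  type <- match.arg(type)
  if (length(seqs) < 2L) abort("need at least 2 sequences to align")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  if (is.null(submat)) submat <- default_submat(type)
  gp <- default_gap(type)
  if (is.null(gap_open)) gap_open <- gp[["open"]]
  if (is.null(gap_extend)) gap_extend <- gp[["extend"]]
  n <- length(seqs)
  ids <- names(seqs)
  if (n == 2L) {
    pa <- pairwise_align(seqs[[1]], seqs[[2]], type, submat, gap_open, gap_extend)
    return(new_alignment(setNames(pa$alignment, ids), type))
  }
  idm <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    pid <- pairwise_align(seqs[[i]], seqs[[j]], type, submat,
                          gap_open, gap_extend)$identity
    idm[i, j] <- idm[j, i] <- pid
  }
  # guide tree: UPGMA on identity distance, leaves in lexicographic id order
  # so equal-distance joins resolve deterministically
  ord <- order(ids)
  d <- as.dist(1 - idm[ord, ord] / 100)
  hc <- hclust(d, method = "average")
  alphabet <- rownames(submat)
  clusters <- lapply(ids[ord], function(id) {
    m <- matrix(chars(seqs[[id]]), nrow = 1)
    list(ids = id, mat = m)
  })
  merged <- vector("list", nrow(hc$merge))
  get_cluster <- function(k) if (k < 0) clusters[[-k]] else merged[[k]]
  for (s in seq_len(nrow(hc$merge))) {
    A <- get_cluster(hc$merge[s, 1])
    B <- get_cluster(hc$merge[s, 2])
    PA <- profile_of(A$mat, alphabet)
    PB <- profile_of(B$mat, alphabet)
    M <- PA %*% submat %*% t(PB)
    res <- gotoh_align_cpp(M, gap_open, gap_extend)
    newA <- expand_by_path(A$mat, res$path_a)
    newB <- expand_by_path(B$mat, res$path_b)
    merged[[s]] <- list(ids = c(A$ids, B$ids), mat = rbind(newA, newB))
  }
  final <- merged[[nrow(hc$merge)]]
  aligned <- setNames(apply(final$mat, 1, paste, collapse = ""), final$ids)
  new_alignment(aligned[ids], type)
}

expand_by_path <- function(mat, path) {
  out <- matrix("-", nrow(mat), length(path))
  keep <- path != 0L
  out[, keep] <- mat[, path[keep], drop = FALSE]
  out
}

#' Percent-identity matrix from a multiple alignment
#'
#' For each pair of rows, columns gapped in both members are skipped;
#' identity is the number of identical (ungapped, equal) columns divided by
#' the remaining columns (`denominator = "aligned"`), or by the shorter
#' ungapped sequence length (`"shorter"`), as a percentage.
#'
#' @param aln An `alignment` object.
#' @param denominator Identity convention, see above.
#' @return An `identity_matrix`: a symmetric numeric matrix of percentages
#'   with 100 on the diagonal.
#' @export
identity_matrix <- function(aln, denominator = c("aligned", "shorter")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(aln, "alignment"))
  m <- as.matrix(aln)
  n <- nrow(m)
  ids <- aln$ids
  out <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(max(n - 1, 0))) for (j in (i + 1):n) {
    gi <- m[i, ] == "-"; gj <- m[j, ] == "-"
    use <- !(gi & gj)
    matches <- sum(m[i, use] == m[j, use] & !gi[use] & !gj[use])
    den <- if (denominator == "aligned") sum(use) else min(sum(!gi), sum(!gj))
    out[i, j] <- out[j, i] <- 100 * matches / den
  }
  structure(out, class = c("identity_matrix", "matrix", "array"))
}

#' @export
print.identity_matrix <- function(x, ...) {
  cat(sprintf("<identity_matrix> %d x %d, mean off-diagonal %.1f%%\n",
              nrow(x), ncol(x), mean_offdiag(x)))
  print(round(unclass(x), 1))
  invisible(x)
}

#' Summaries of an identity matrix
#'
#' `mean_offdiag()` is the mean of all off-diagonal entries; `row_means()`
#' gives each sequence's mean identity to all others.
#'
#' @param x An `identity_matrix`.
#' @return A number, or a named numeric vector.
#' @export
mean_offdiag <- function(x) {
  n <- nrow(x)
  if (n < 2) return(NA_real_)
  mean(x[upper.tri(x)])
}

#' @rdname mean_offdiag
#' @export
row_means_offdiag <- function(x) {
  n <- nrow(x)
  (rowSums(x) - diag(x)) / (n - 1)
}

#' @exportS3Method generics::tidy
tidy.identity_matrix <- function(x, ...) {
  as_tibble(as.table(unclass(x)), .name_repair = "minimal") %>%
    setNames(c("id_a", "id_b", "identity")) %>%
    as_tibble()
}

#' @exportS3Method generics::glance
glance.identity_matrix <- function(x, ...) {
  rm <- row_means_offdiag(x)
  tibble(n = nrow(x), mean_identity = mean_offdiag(x),
         min_row_mean = min(rm), min_row_id = names(rm)[which.min(rm)])
}

#' Heatmap of an identity matrix
#'
#' @param object An `identity_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.identity_matrix <- function(object, ...) {
  df <- tidy.identity_matrix(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$id_a, .data$id_b,
                                   fill = .data$identity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100), name = "% identity") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
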