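AA20 <- ALPHABETS$protein[1:20]

aa_encode <- function(x) {
  # 1..20 standard residues, 21 = X / anything else (scores zero)
  code <- match(chars(x), AA20)
  code[is.na(code)] <- 21L
  code
}

#' Construct a protein motif model
#'
#' A motif model is a position-frequency matrix (rows = positions, columns
#' = the 20 standard residues), its consensus (most frequent residue per
#' position), and a background composition used for log-odds scoring.
#'
#' @param id Motif identifier.
#' @param pfm Numeric matrix, width x 20, each row summing to 1.
#' @param background Named length-20 residue frequency vector.
#' @return A `motif_model` object.
#' @export
motif_model <- function(id, pfm, background = rep(1 / 20, 20)) {
  stopifnot(ncol(pfm) == 20, all(abs(rowSums(pfm) - 1) < 1e-9))
  colnames(pfm) <- AA20
  names(background) <- AA20
  consensus <- paste(AA20[apply(pfm, 1, which.max)], collapse = "")
  ic <- sum(rowSums(pfm * log2(sweep(pfm, 2, background, "/"))))
  structure(list(id = id, width = nrow(pfm), pfm = pfm,
                 consensus = consensus, background = background,
                 ic = ic),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("<motif_model> %s width %d IC %.1f bits\n  consensus %s\n",
              x$id, x$width, x$ic, x$consensus))
  invisible(x)
}

score_matrix <- function(motif) {
  s <- log2(sweep(motif$pfm, 2, motif$background, "/"))
  cbind(s, X = 0)  # unknown residues are scoring-neutral
}

build_motif_from_block <- function(id, block, background, pseudocount = 0.01) {
  # block: character matrix (rows = sequences, cols = motif columns);
  # gap characters are ignored in the per-column counts
  W <- ncol(block)
  pfm <- matrix(pseudocount, W, 20, dimnames = list(NULL, AA20))
  for (j in seq_len(W)) {
    tab <- table(factor(block[, j], levels = AA20))
    pfm[j, ] <- pfm[j, ] + as.numeric(tab)
  }
  pfm <- pfm / rowSums(pfm)
  motif_model(id, pfm, background)
}

#' Extract conserved motif models from a seed alignment
#'
#' Scores each alignment column by its information content (in bits)
#' against the seed-set background composition, then reports maximal runs
#' of columns with IC at or above `ic_threshold` and gap fraction at most
#' `max_gap_frac`. Runs shorter than `min_width` are dropped; runs longer
#' than `max_width` are split into near-equal pieces. Motifs are numbered
#' `M1, M2, ...` by decreasing total information content, mirroring how
#' motif-discovery tools rank by conservation.
#'
#' @param aln An `alignment` of at least 3 seed proteins.
#' @param min_width,max_width Width bounds in residues (defaults 7 and 50).
#' @param max_motifs Keep at most this many motifs.
#' @param ic_threshold Per-column information content cutoff in bits.
#' @param max_gap_frac Maximum fraction of gap characters per column.
#' @param min_dominance Minimum frequency of the most common residue in a
#'   conserved column. This guards against the small-sample inflation of
#'   information content: with few sequences a column of entirely distinct
#'   residues can still reach ~2 bits, but its top residue frequency stays
#'   low.
#' @param pseudocount Added to each PFM cell before normalization.
#' @return A `motif_set`: list of `motif_model` objects, each carrying the
#'   alignment column span it was extracted from (`aln_start`, `aln_end`).
#' @export
discover_motifs <- function(aln, min_width = 7, max_width = 50,
                            max_motifs = 13, ic_threshold = 2.0,
                            max_gap_frac = 0.2, min_dominance = 0.5,
                            pseudocount = 0.01) {
  stopifnot(inherits(aln, "alignment"))
  if (length(aln$aligned) < 3L) abort("need at least 3 seed sequences")
  m <- as.matrix(aln)
  bg <- background_freqs(degap(aln$aligned))
  L <- ncol(m)
  ic <- numeric(L); gapf <- numeric(L); dom <- numeric(L)
  for (j in seq_len(L)) {
    col <- m[, j]
    gapf[j] <- mean(col == "-")
    res <- col[col != "-"]
    if (!length(res)) { ic[j] <- 0; next }
    counts <- as.numeric(table(factor(res, levels = AA20)))
    dom[j] <- max(counts) / length(res)
    p <- (counts + pseudocount)
    p <- p / sum(p)
    ic[j] <- sum(p * log2(p / bg))
  }
  # insertion columns (gapped in the vast majority of rows) are masked
  # before run-finding so a rare one-sequence insertion cannot split a
  # conserved block below min_width
  visible <- which(gapf < 0.8)
  ok_vis <- ic[visible] >= ic_threshold & gapf[visible] <= max_gap_frac &
    dom[visible] >= min_dominance
  if (!any(ok_vis)) {
    warn("no alignment column passes the information-content threshold")
    return(structure(list(), class = "motif_set"))
  }
  runs <- rle_runs(ok_vis)
  runs <- runs[(runs$end - runs$start + 1) >= min_width, , drop = FALSE]
  blocks <- list()  # each block: vector of original column indices
  for (r in seq_len(nrow(runs))) {
    s <- runs$start[r]; e <- runs$end[r]
    len <- e - s + 1
    npieces <- ceiling(len / max_width)
    cuts <- floor(seq(s, e + 1, length.out = npieces + 1))
    for (p in seq_len(npieces)) {
      ps <- cuts[p]; pe <- cuts[p + 1] - 1
      if (pe - ps + 1 >= min_width) {
        blocks[[length(blocks) + 1]] <- visible[ps:pe]
      }
    }
  }
  if (!length(blocks)) {
    warn("no conserved block satisfies the width bounds")
    return(structure(list(), class = "motif_set"))
  }
  models <- lapply(blocks, function(b) {
    mod <- build_motif_from_block("tmp", m[, b, drop = FALSE], bg,
                                  pseudocount)
    mod$aln_start <- min(b); mod$aln_end <- max(b)
    mod
  })
  ord <- order(vapply(models, `[[`, numeric(1), "ic"), decreasing = TRUE)
  models <- models[ord][seq_len(min(length(models), max_motifs))]
  for (i in seq_along(models)) models[[i]]$id <- paste0("M", i)
  structure(models, class = "motif_set")
}

background_freqs <- function(seqs, pseudocount = 0.01) {
  tab <- table(factor(unlist(strsplit(seqs, "")), levels = AA20))
  p <- as.numeric(tab) + pseudocount
  setNames(p / sum(p), AA20)
}

rle_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' @export
print.motif_set <- function(x, ...) {
  cat(sprintf("<motif_set> %d motifs\n", length(x)))
  for (m in x) {
    cat(sprintf("  %s w=%d IC=%.1f %s\n", m$id, m$width, m$ic, m$consensus))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.motif_set <- function(x, ...) {
  tibble(
    motif_id = vapply(x, `[[`, character(1), "id"),
    width = vapply(x, `[[`, integer(1), "width"),
    ic = vapply(x, `[[`, numeric(1), "ic"),
    consensus = vapply(x, `[[`, character(1), "consensus")
  )
}

#' @exportS3Method generics::glance
glance.motif_set <- function(x, ...) {
  w <- vapply(x, `[[`, integer(1), "width")
  tibble(n_motifs = length(x),
         min_width = if (length(w)) min(w) else NA_integer_,
         max_width = if (length(w)) max(w) else NA_integer_,
         total_ic = sum(vapply(x, `[[`, numeric(1), "ic")))
}

no_hit <- function(protein_id, motif_id) {
  tibble(protein_id = protein_id, motif_id = motif_id,
         start = integer(), end = integer(),
         logodds = numeric(), consensus_identity = numeric())[0, ]
}

#' Scan a protein for the best occurrence of a motif
#'
#' Slides the motif over the protein and scores each window by summed
#' log-odds `log2(pfm / background)`; unknown residues (X) score zero.
#' Returns the best-scoring window (ties broken by smallest start) together
#' with its fractional identity to the motif consensus.
#'
#' @param protein A single amino-acid string.
#' @param motif A `motif_model`.
#' @param protein_id Id used in the output.
#' @return A one-row tibble (`protein_id`, `motif_id`, `start`, `end`,
#'   `logodds`, `consensus_identity`), or a zero-row tibble when the
#'   protein is shorter than the motif (a no-hit, distinct from a
#'   low-scoring hit).
#' @export
scan_protein <- function(protein, motif, protein_id = "protein") {
  if (nchar(protein) < motif$width) return(no_hit(protein_id, motif$id))
  sw <- scan_windows_cpp(aa_encode(protein), score_matrix(motif),
                         aa_encode(motif$consensus))
  best <- which.max(sw$logodds)
  tibble(protein_id = protein_id, motif_id = motif$id,
         start = as.integer(best), end = as.integer(best + motif$width - 1L),
         logodds = sw$logodds[best], consensus_identity = sw$identity[best])
}

#' All presence-called occurrences of a motif in a protein
#'
#' Like [scan_protein()] but returns every window that passes the presence
#' call, after greedily removing overlaps (best score first).
#'
#' @inheritParams scan_protein
#' @inheritParams call_presence
#' @return A tibble of hits (possibly zero rows).
#' @export
scan_protein_all <- function(protein, motif, protein_id = "protein",
                             identity_threshold = 0.6) {
  if (nchar(protein) < motif$width) return(no_hit(protein_id, motif$id))
  sw <- scan_windows_cpp(aa_encode(protein), score_matrix(motif),
                         aa_encode(motif$consensus))
  pass <- which(sw$identity >= identity_threshold & sw$logodds > 0)
  if (!length(pass)) return(no_hit(protein_id, motif$id))
  pass <- pass[order(-sw$logodds[pass], pass)]
  kept <- integer()
  for (s in pass) {
    if (!any(abs(kept - s) < motif$width)) kept <- c(kept, s)
  }
  kept <- sort(kept)
  tibble(protein_id = protein_id, motif_id = motif$id,
         start = kept, end = kept + motif$width - 1L,
         logodds = sw$logodds[kept], consensus_identity = sw$identity[kept])
}

#' Presence call for motif hits
#'
#' A hit counts as a present motif when its identity to the motif
#' consensus reaches `identity_threshold` and its log-odds score is
#' positive. The default 0.6 is deliberately permissive: diverged but
#' homologous motif copies in this family retain roughly 70% consensus
#' identity.
#'
#' @param hits A tibble of hits from [scan_protein()].
#' @param identity_threshold Minimum fraction of consensus-identical
#'   positions.
#' @return The tibble with a logical `present` column added.
#' @export
call_presence <- function(hits, identity_threshold = 0.6) {
  dplyr::mutate(hits, present = .data$consensus_identity >=
                  identity_threshold & .data$logodds > 0)
}

#' Motif architecture of proteins
#'
#' Scans each protein with every motif, keeps presence-called best hits,
#' resolves overlaps (higher log-odds wins; ties go to the
#' smaller-numbered motif) and orders hits by start position, giving the
#' linear motif architecture of each protein.
#'
#' @param proteins Named character vector of protein sequences.
#' @param motifs A `motif_set`.
#' @param identity_threshold Passed to [call_presence()].
#' @return A tibble of retained hits sorted by protein and start, with
#'   class `motif_architecture`.
#' @export
architecture <- function(proteins, motifs, identity_threshold = 0.6) {
  if (!length(proteins)) {
    out <- tibble(protein_id = character(), motif_id = character(),
                  start = integer(), end = integer(), logodds = numeric(),
                  consensus_identity = numeric())
    return(structure(out, class = c("motif_architecture", class(out)),
                     motif_ids = motif_ids(motifs)))
  }
  if (is.null(names(proteins))) names(proteins) <- paste0("p", seq_along(proteins))
  rows <- purrr::map_dfr(names(proteins), function(id) {
    hits <- purrr::map_dfr(motifs, function(m) {
      scan_protein(proteins[[id]], m, protein_id = id)
    })
    hits <- dplyr::filter(call_presence(hits, identity_threshold),
                          .data$present)
    resolve_overlaps(hits)
  })
  rows <- dplyr::arrange(rows, .data$protein_id, .data$start)
  structure(rows, class = c("motif_architecture", class(rows)),
            motif_ids = motif_ids(motifs))
}

#' Ids of the motifs in a motif set
#'
#' @param motifs A `motif_set`.
#' @return Character vector of motif ids.
#' @export
motif_ids <- function(motifs) vapply(motifs, `[[`, character(1), "id")

motif_rank <- function(id) as.integer(sub("^M", "", id))

resolve_overlaps <- function(hits) {
  if (nrow(hits) < 2) return(dplyr::select(hits, -dplyr::any_of("present")))
  ord <- order(-hits$logodds, motif_rank(hits$motif_id))
  hits <- hits[ord, ]
  kept <- hits[0, ]
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    if (!nrow(kept) || all(h$start > kept$end | h$end < kept$start)) {
      kept <- dplyr::bind_rows(kept, h)
    }
  }
  dplyr::select(kept, -dplyr::any_of("present"))
}

#' Presence/absence matrix of a motif architecture
#'
#' @param arch A `motif_architecture` tibble.
#' @param proteins Optional character vector fixing the row order (ids with
#'   no hits appear as all-absent rows).
#' @return Logical matrix, proteins x motifs.
#' @export
presence_matrix <- function(arch, proteins = NULL) {
  mids <- attr(arch, "motif_ids")
  pids <- proteins %||% unique(arch$protein_id)
  out <- matrix(FALSE, length(pids), length(mids),
                dimnames = list(pids, mids))
  if (nrow(arch)) {
    keep <- arch$protein_id %in% pids
    out[cbind(arch$protein_id[keep], arch$motif_id[keep])] <- TRUE
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Percent identity between two motif consensus sequences
#'
#' Global alignment of the two consensus strings (BLOSUM62, affine gaps);
#' identity is identical columns over alignment columns, as a percentage.
#' Used to match motif catalogues built from different genotypes.
#'
#' @param a,b `motif_model` objects (or plain consensus strings).
#' @return Percent identity in `[0, 100]`.
#' @export
compare_motifs <- function(a, b) {
  ca <- if (inherits(a, "motif_model")) a$consensus else a
  cb <- if (inherits(b, "motif_model")) b$consensus else b
  pairwise_align(ca, cb, type = "protein")$identity
}

#' Serialize / load motif sets
#'
#' Motif sets are written as two TSVs: `<prefix>_motifs.tsv` (id, width,
#' ic, consensus) and `<prefix>_pfm.tsv` (long form: motif_id, position,
#' residue, frequency, plus the background as position 0).
#'
#' @param motifs A `motif_set`.
#' @param prefix Path prefix for the two files.
#' @return The prefix, invisibly.
#' @export
write_motifs <- function(motifs, prefix) {
  readr::write_tsv(tidy.motif_set(motifs), paste0(prefix, "_motifs.tsv"),
                   progress = FALSE)
  pfm <- purrr::map_dfr(motifs, function(m) {
    dplyr::bind_rows(
      tibble(motif_id = m$id, position = 0L, residue = AA20,
             frequency = unname(m$background)),
      tibble(motif_id = m$id,
             position = rep(seq_len(m$width), each = 20),
             residue = rep(AA20, m$width),
             frequency = as.vector(t(m$pfm)))
    )
  })
  readr::write_tsv(pfm, paste0(prefix, "_pfm.tsv"), progress = FALSE)
  invisible(prefix)
}

#' @rdname write_motifs
#' @export
read_motifs <- function(prefix) {
  meta <- readr::read_tsv(paste0(prefix, "_motifs.tsv"),
                          col_types = "cidc", progress = FALSE)
  pfm <- readr::read_tsv(paste0(prefix, "_pfm.tsv"),
                         col_types = "cicd", progress = FALSE)
  models <- lapply(seq_len(nrow(meta)), function(i) {
    id <- meta$motif_id[i]
    sub <- dplyr::filter(pfm, .data$motif_id == id)
    bg <- dplyr::filter(sub, .data$position == 0L)
    bgv <- setNames(bg$frequency, bg$residue)[AA20]
    body <- dplyr::filter(sub, .data$position > 0L)
    W <- max(body$position)
    mat <- matrix(0, W, 20, dimnames = list(NULL, AA20))
    mat[cbind(body$position, match(body$residue, AA20))] <- body$frequency
    motif_model(id, mat, bgv)
  })
  structure(models, class = "motif_set")
}

#' Plot motif architectures
#'
#' Draws each protein as a horizontal track with its presence-called
#' motifs as colored blocks, the classic family-architecture figure.
#'
#' @param arch A `motif_architecture` tibble.
#' @param protein_lengths Optional named vector of protein lengths used to
#'   draw track backbones.
#' @return A ggplot object.
#' @export
plot_architecture <- function(arch, protein_lengths = NULL) {
  p <- ggplot2::ggplot(arch)
  if (!is.null(protein_lengths)) {
    back <- tibble(protein_id = names(protein_lengths),
                   len = unname(protein_lengths))
    p <- p + ggplot2::geom_segment(
      data = back,
      ggplot2::aes(x = 1, xend = .data$len, y = .data$protein_id,
                   yend = .data$protein_id),
      linewidth = 0.3, color = "grey60")
  }
  p + ggplot2::geom_tile(
    ggplot2::aes(x = (.data$start + .data$end) / 2, y = .data$protein_id,
                 width = .data$end - .data$start + 1, fill = .data$motif_id),
    height = 0.7) +
    ggplot2::labs(x = "residue position", y = NULL, fill = "motif") +
    ggplot2::theme_minimal()
}

#' Motifs in spatial (N- to C-terminal) order
#'
#' Orders a discovered `motif_set` by its position in the seed alignment,
#' giving the architecture order; the first and last elements are the
#' natural anchor motifs for the genome scan.
#'
#' @param motifs A `motif_set` whose models carry `aln_start` (as produced
#'   by [discover_motifs()]).
#' @return Character vector of motif ids in spatial order.
#' @export
spatial_order <- function(motifs) {
  starts <- vapply(motifs, function(m) m$aln_start %||% NA_integer_,
                   numeric(1))
  if (any(is.na(starts))) {
    abort("motif set carries no alignment coordinates")
  }
  motif_ids(motifs)[order(starts)]
}
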