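IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

validate_iupac <- function(pattern, name = pattern) {
  bad <- setdiff(chars(pattern), names(IUPAC_SETS))
  if (length(bad)) {
    abort(sprintf("invalid IUPAC code '%s' in pattern '%s'", bad[1], name))
  }
  invisible(pattern)
}

iupac_starts_forward <- function(seq, pattern) {
  m <- Biostrings::matchPattern(pattern, Biostrings::DNAString(seq),
                                fixed = FALSE)
  as.integer(Biostrings::start(m))
}

iupac_count_forward <- function(seq, pattern) {
  length(iupac_starts_forward(seq, pattern))
}

#' Extract upstream promoter regions
#'
#' Takes the region of `length` bases immediately upstream of each
#' annotated gene start (the TSS proxy), oriented 5'-to-3' in the
#' transcription direction: for a plus-strand gene starting at `s` this is
#' the forward-strand interval `[s - length, s - 1]` (1-based); for a
#' minus-strand gene ending at `e` it is `[e + 1, e + length]`
#' reverse-complemented. Regions truncated by a chromosome edge are
#' flagged `clipped`.
#'
#' @param annotations Tibble as from [read_gff3()].
#' @param genome Named character vector of chromosome sequences.
#' @param length Promoter length in nt (default 3000).
#' @return A tibble (`gene_id`, `seq_id`, `strand`, `start`, `end` genomic
#'   1-based coordinates of the region, `sequence`, `clipped`).
#' @export
extract_promoters <- function(annotations, genome, length = 3000) {
  missing <- setdiff(annotations$seq_id, names(genome))
  if (base::length(missing)) {
    abort(paste0("sequence absent from genome: ", missing[1]))
  }
  rows <- purrr::map_dfr(seq_len(nrow(annotations)), function(i) {
    a <- annotations[i, ]
    chrlen <- nchar(genome[[a$seq_id]])
    if (a$strand == "+") {
      s <- max(1L, a$start - length)
      e <- a$start - 1L
      if (e < s) abort(paste0("gene at chromosome start has no promoter: ",
                              a$gene_id))
      seq <- substr(genome[[a$seq_id]], s, e)
    } else {
      s <- a$end + 1L
      e <- min(chrlen, a$end + length)
      if (e < s) abort(paste0("gene at chromosome end has no promoter: ",
                              a$gene_id))
      seq <- revcomp(substr(genome[[a$seq_id]], s, e))
    }
    clipped <- nchar(seq) < length
    if (clipped) {
      warn(sprintf("promoter of %s clipped to %d nt at a chromosome edge",
                   a$gene_id, nchar(seq)))
    }
    tibble(gene_id = a$gene_id, seq_id = a$seq_id, strand = a$strand,
           start = s, end = e, sequence = seq, clipped = clipped)
  })
  rows
}

#' Census of IUPAC cis-elements over promoter regions
#'
#' Finds every (by default overlapping) occurrence of each degenerate
#' IUPAC pattern in each promoter sequence and, when `strands = "both"`,
#' on its reverse complement as well. Positions are reported relative to
#' the TSS (position -1 is the base adjacent to the gene start). For
#' palindromic patterns in both-strand mode, the reverse-strand hit at the
#' same interval as a forward hit is suppressed so each site is counted
#' once.
#'
#' @param regions Tibble from [extract_promoters()], or any tibble with
#'   `gene_id` and `sequence` columns.
#' @param patterns Tibble with columns `name` and `iupac`.
#' @param strands `"both"` (default, the PLACE-style convention) or
#'   `"forward"`.
#' @param overlapping Count overlapping occurrences (default TRUE).
#' @return An `element_census` tibble of occurrences (`gene_id`,
#'   `element`, `position`, `strand`), carrying the promoter and element
#'   universes as attributes so zero counts are recoverable.
#' @export
scan_elements <- function(regions, patterns,
                          strands = c("both", "forward"),
                          overlapping = TRUE) {
  strands <- match.arg(strands)
  purrr::walk2(patterns$iupac, patterns$name, validate_iupac)
  rows <- purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    seq <- regions$sequence[i]
    plen <- nchar(seq)
    purrr::map_dfr(seq_len(nrow(patterns)), function(p) {
      pat <- patterns$iupac[p]
      w <- nchar(pat)
      fwd <- iupac_starts_forward(seq, pat)
      if (!overlapping) fwd <- drop_overlaps(fwd, w)
      out <- tibble(gene_id = regions$gene_id[i],
                    element = patterns$name[p],
                    position = fwd - plen - 1L,
                    strand = "+")
      if (strands == "both" && revcomp(pat) != pat) {
        rev <- iupac_starts_forward(seq, revcomp(pat))
        if (!overlapping) rev <- drop_overlaps(rev, w)
        out <- dplyr::bind_rows(out, tibble(
          gene_id = regions$gene_id[i], element = patterns$name[p],
          position = rev - plen - 1L, strand = "-"))
      }
      out
    })
  })
  structure(dplyr::arrange(rows, .data$gene_id, .data$element,
                           .data$position),
            class = c("element_census", class(rows)),
            gene_ids = regions$gene_id,
            elements = patterns$name)
}

drop_overlaps <- function(starts, width) {
  starts <- sort(starts)
  kept <- integer()
  last_end <- -1L
  for (s in starts) {
    if (s > last_end) { kept <- c(kept, s); last_end <- s + width - 1L }
  }
  kept
}

#' Promoter-by-element count table
#'
#' @param census An `element_census` from [scan_elements()].
#' @return A tibble, one row per promoter, one column per element,
#'   containing occurrence counts (zeros included).
#' @export
element_counts <- function(census) {
  gids <- attr(census, "gene_ids")
  els <- attr(census, "elements")
  full <- tidyr::expand_grid(gene_id = gids, element = els)
  counts <- census %>%
    dplyr::count(.data$gene_id, .data$element, name = "count")
  full %>%
    dplyr::left_join(counts, by = c("gene_id", "element")) %>%
    dplyr::mutate(count = tidyr::replace_na(.data$count, 0L)) %>%
    tidyr::pivot_wider(names_from = "element", values_from = "count")
}

#' Elements present in every promoter
#'
#' @param census An `element_census`.
#' @return Character vector of elements with at least one occurrence in
#'   each promoter.
#' @export
elements_in_all <- function(census) {
  gids <- attr(census, "gene_ids")
  if (!length(gids)) abort("census covers no promoters")
  tab <- census %>%
    dplyr::distinct(.data$gene_id, .data$element) %>%
    dplyr::count(.data$element, name = "n_promoters")
  sort(tab$element[tab$n_promoters == length(gids)])
}

#' Elements unique to one promoter
#'
#' @param census An `element_census`.
#' @param focal A promoter (gene) id present in the census.
#' @return Character vector of elements occurring in `focal` and in no
#'   other promoter.
#' @export
unique_elements <- function(census, focal) {
  gids <- attr(census, "gene_ids")
  if (!focal %in% gids) abort(paste0("unknown promoter id: ", focal))
  present <- census %>% dplyr::distinct(.data$gene_id, .data$element)
  in_focal <- present$element[present$gene_id == focal]
  elsewhere <- present$element[present$gene_id != focal]
  sort(setdiff(in_focal, elsewhere))
}

#' Percent-identity matrix of promoter regions
#'
#' Aligns the promoter sequences with [progressive_msa()] under DNA
#' scoring and computes the [identity_matrix()].
#'
#' @param regions Tibble from [extract_promoters()].
#' @param ... Passed to [identity_matrix()] (e.g. `denominator`).
#' @return An `identity_matrix`.
#' @export
promoter_identity <- function(regions, ...) {
  if (nrow(regions) < 2) abort("need at least 2 promoter regions")
  seqs <- setNames(regions$sequence, regions$gene_id)
  identity_matrix(progressive_msa(seqs, type = "dna"), ...)
}

#' Heatmap of element counts across promoters
#'
#' @param census An `element_census`.
#' @return A ggplot object.
#' @export
plot_element_census <- function(census) {
  long <- element_counts(census) %>%
    tidyr::pivot_longer(-"gene_id", names_to = "element",
                        values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(.data$element, .data$gene_id,
                                     fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "count") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Write promoter regions as FASTA plus BED
#'
#' The BED file carries the genomic intervals (0-based half-open) of the
#' regions; the FASTA carries the transcription-oriented sequences.
#'
#' @param regions Tibble from [extract_promoters()].
#' @param prefix Output path prefix.
#' @return The prefix, invisibly.
#' @export
write_promoters <- function(regions, prefix) {
  write_fasta(setNames(regions$sequence, regions$gene_id),
              paste0(prefix, "_promoters.fasta"))
  bed <- dplyr::transmute(regions, .data$seq_id,
                          start0 = .data$start - 1L, end0 = .data$end,
                          name = .data$gene_id, score = 0L,
                          strand = .data$strand)
  readr::write_tsv(bed, paste0(prefix, "_promoters.bed"),
                   col_names = FALSE, progress = FALSE)
  invisible(prefix)
}
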