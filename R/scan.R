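#' Six-frame translation with residue-to-genome coordinate maps
#'
#' Translates a nucleotide sequence in all six frames (0-2 forward, 0-2 on
#' the reverse complement) with the standard codon table. Stop codons are
#' emitted as `*`; any codon containing N translates to X. Each track
#' carries enough information to map any residue span back to its
#' forward-strand genomic interval (0-based half-open) via
#' [residue_interval()].
#'
#' @param seq A single nucleotide string.
#' @param seq_id Id recorded on the tracks.
#' @return A list of 6 track lists (`seq_id`, `strand`, `frame`,
#'   `protein`, `seq_len`).
#' @export
six_frame_translate <- function(seq, seq_id = "seq") {
  L <- nchar(seq)
  rc <- revcomp(seq)
  tracks <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc
    for (f in 0:2) {
      ncod <- (L - f) %/% 3
      if (ncod < 1) {
        prot <- ""
      } else {
        sub <- substr(s, f + 1L, f + 3L * ncod)
        prot <- as.character(Biostrings::translate(
          Biostrings::DNAString(sub), if.fuzzy.codon = "X"))
      }
      tracks[[length(tracks) + 1]] <- list(seq_id = seq_id, strand = strand,
                                           frame = f, protein = prot,
                                           seq_len = L)
    }
  }
  tracks
}

#' Map a residue span of a translation track to genomic coordinates
#'
#' @param track One track from [six_frame_translate()].
#' @param res_start,res_end 1-based residue positions (inclusive).
#' @return Forward-strand 0-based half-open interval `c(start, end)`.
#' @export
residue_interval <- function(track, res_start, res_end) {
  f <- track$frame
  if (track$strand == "+") {
    c(f + 3L * (res_start - 1L), f + 3L * res_end)
  } else {
    L <- track$seq_len
    c(L - f - 3L * res_end, L - f - 3L * (res_start - 1L))
  }
}

#' Locate anchor-motif occurrences on all translation tracks
#'
#' Scans every track for presence-called occurrences of the designated
#' N-terminal-most (`first_motif`) and C-terminal-most (`last_motif`)
#' motifs of the seed architecture. Occurrences overlapping a stop codon
#' are discarded.
#'
#' @param tracks Tracks from [six_frame_translate()].
#' @param first_motif,last_motif `motif_model`s chosen as anchors.
#' @param identity_threshold Presence-call threshold.
#' @return Tibble of anchor hits: `track` (index), `seq_id`, `strand`,
#'   `frame`, `anchor` ("first"/"last"), `res_start`, `res_end`,
#'   `g_start`, `g_end` (0-based half-open, forward strand), `logodds`,
#'   `consensus_identity`.
#' @export
find_anchors <- function(tracks, first_motif, last_motif,
                         identity_threshold = 0.6) {
  anchor_models <- list(first = first_motif, last = last_motif)
  purrr::map_dfr(seq_along(tracks), function(ti) {
    tr <- tracks[[ti]]
    purrr::map_dfr(names(anchor_models), function(which_anchor) {
      am <- list(anchor = which_anchor, motif = anchor_models[[which_anchor]])
      hits <- scan_protein_all(tr$protein, am$motif, protein_id = tr$seq_id,
                               identity_threshold = identity_threshold)
      if (!nrow(hits)) return(NULL)
      hits <- hits[!stop_in_span(tr$protein, hits$start, hits$end), ,
                   drop = FALSE]
      if (!nrow(hits)) return(NULL)
      g <- t(mapply(function(s, e) residue_interval(tr, s, e),
                    hits$start, hits$end))
      tibble(track = ti, seq_id = tr$seq_id, strand = tr$strand,
             frame = tr$frame, anchor = am$anchor,
             res_start = hits$start, res_end = hits$end,
             g_start = g[, 1], g_end = g[, 2],
             logodds = hits$logodds,
             consensus_identity = hits$consensus_identity)
    })
  })
}

stop_in_span <- function(protein, start, end) {
  mapply(function(s, e) grepl("*", substr(protein, s, e), fixed = TRUE),
         start, end)
}

#' Anchor window offsets from the seed architecture
#'
#' The scan extends anchor hits to full-length candidate windows using the
#' seed family's empirical geometry: `first` is the mean number of
#' residues preceding the first anchor motif across the seed proteins, and
#' `last` the mean number following the last anchor motif.
#'
#' @param seed_proteins Named character vector of seed proteins.
#' @param motifs A `motif_set`.
#' @param first_id,last_id Ids of the anchor motifs within `motifs`.
#' @param identity_threshold Presence-call threshold.
#' @return Named numeric vector `c(first = ..., last = ...)` (rounded).
#' @export
anchor_offsets <- function(seed_proteins, motifs, first_id, last_id,
                           identity_threshold = 0.6) {
  arch <- architecture(seed_proteins, motifs, identity_threshold)
  firsts <- dplyr::filter(arch, .data$motif_id == first_id)
  lasts <- dplyr::filter(arch, .data$motif_id == last_id)
  lens <- nchar(seed_proteins)
  c(first = round(mean(firsts$start - 1L)),
    last = round(mean(lens[lasts$protein_id] - lasts$end)))
}

#' Build candidate paralog windows from anchor hits
#'
#' Paired anchors (a first anchor followed by a last anchor on the same
#' track within `1.5 * target_len` residues) delimit a window from
#' `first_start - offsets["first"]` to `last_end + offsets["last"]`. A
#' lone first anchor opens a window of `target_len` residues starting at
#' `first_start - offsets["first"]`; a lone last anchor a window of
#' `target_len` residues ending at `last_end + offsets["last"]`. Windows
#' are clipped to the stop-free track segment containing the anchor(s) and
#' to the track bounds; candidates shorter than `min_length` residues are
#' discarded.
#'
#' @param anchors Tibble from [find_anchors()].
#' @param tracks The matching tracks.
#' @param target_len Full-length protein target in residues (default 280).
#' @param offsets Named vector from [anchor_offsets()].
#' @param min_length Minimum candidate protein length (default 90).
#' @return Tibble of candidates: `seq_id`, `strand`, `frame`, `g_start`,
#'   `g_end` (0-based half-open), `res_start`, `res_end`, `protein`.
#' @export
build_candidates <- function(anchors, tracks, target_len = 280,
                             offsets = c(first = 0, last = 0),
                             min_length = 90) {
  if (!nrow(anchors)) {
    return(tibble(seq_id = character(), strand = character(),
                  frame = integer(), g_start = integer(), g_end = integer(),
                  res_start = integer(), res_end = integer(),
                  protein = character()))
  }
  off_f <- as.integer(offsets[["first"]])
  off_l <- as.integer(offsets[["last"]])
  out <- purrr::map_dfr(unique(anchors$track), function(ti) {
    tr <- tracks[[ti]]
    prot_chars <- chars(tr$protein)
    seg <- cumsum(c(TRUE, head(prot_chars, -1) == "*"))  # segment index
    a <- dplyr::arrange(dplyr::filter(anchors, .data$track == ti),
                        .data$res_start)
    a$segment <- seg[a$res_start]
    windows <- list()
    for (sg in unique(a$segment)) {
      sa <- a[a$segment == sg, ]
      seg_pos <- which(seg == sg & prot_chars != "*")
      seg_lo <- min(seg_pos); seg_hi <- max(seg_pos)
      seg_windows <- list()
      used <- rep(FALSE, nrow(sa))
      # pair first->last greedily, nearest following last anchor
      for (i in which(sa$anchor == "first")) {
        js <- which(sa$anchor == "last" & !used &
                      sa$res_start >= sa$res_end[i] &
                      (sa$res_end - sa$res_start[i] + 1) <= 1.5 * target_len)
        if (length(js)) {
          j <- js[which.min(sa$res_start[js])]
          used[i] <- used[j] <- TRUE
          seg_windows[[length(seg_windows) + 1]] <-
            c(sa$res_start[i] - off_f, sa$res_end[j] + off_l)
        }
      }
      for (i in which(!used)) {
        if (sa$anchor[i] == "first") {
          w0 <- sa$res_start[i] - off_f
          seg_windows[[length(seg_windows) + 1]] <- c(w0, w0 + target_len - 1L)
        } else {
          w1 <- sa$res_end[i] + off_l
          seg_windows[[length(seg_windows) + 1]] <- c(w1 - target_len + 1L, w1)
        }
        used[i] <- TRUE
      }
      seg_windows <- lapply(seg_windows, function(w) {
        c(max(w[1], seg_lo), min(w[2], seg_hi))
      })
      windows <- c(windows, seg_windows)
    }
    purrr::map_dfr(windows, function(w) {
      if (w[2] - w[1] + 1 < min_length) return(NULL)
      g <- residue_interval(tr, w[1], w[2])
      tibble(seq_id = tr$seq_id, strand = tr$strand, frame = tr$frame,
             g_start = g[1], g_end = g[2], res_start = w[1], res_end = w[2],
             protein = substr(tr$protein, w[1], w[2]))
    })
  })
  dplyr::distinct(out)
}

#' Filter candidates by motif content and collapse overlaps
#'
#' Scores every candidate protein against the full motif set, counts
#' presence-called motifs, keeps candidates with at least `min_motifs`
#' (the clade-membership rule: at least three of the nine seed motifs, by
#' default), and collapses overlapping same-strand candidates to one
#' (most motifs wins; ties go to the longer protein, then the smaller
#' genomic start).
#'
#' @param candidates Tibble from [build_candidates()].
#' @param motifs A `motif_set`.
#' @param min_motifs Membership threshold (default 3).
#' @param identity_threshold Presence-call threshold.
#' @return Tibble of members with `n_motifs` added.
#' @export
filter_members <- function(candidates, motifs, min_motifs = 3,
                           identity_threshold = 0.6) {
  if (!nrow(candidates)) {
    return(dplyr::mutate(candidates, n_motifs = integer()))
  }
  n_present <- vapply(candidates$protein, function(p) {
    hits <- purrr::map_dfr(motifs, function(m) scan_protein(p, m))
    sum(call_presence(hits, identity_threshold)$present)
  }, integer(1))
  cand <- dplyr::mutate(candidates, n_motifs = unname(n_present)) %>%
    dplyr::filter(.data$n_motifs >= min_motifs)
  collapse_overlapping(cand)
}

collapse_overlapping <- function(cand) {
  if (nrow(cand) < 2) return(cand)
  cand <- dplyr::arrange(cand, .data$seq_id, .data$strand,
                         dplyr::desc(.data$n_motifs),
                         dplyr::desc(nchar(.data$protein)), .data$g_start)
  kept <- cand[0, ]
  for (i in seq_len(nrow(cand))) {
    x <- cand[i, ]
    same <- kept$seq_id == x$seq_id & kept$strand == x$strand &
      kept$g_start < x$g_end & x$g_start < kept$g_end
    if (!any(same)) kept <- dplyr::bind_rows(kept, x)
  }
  dplyr::arrange(kept, .data$seq_id, .data$g_start)
}

#' Label members as confirming annotation or novel
#'
#' A member overlapping an annotated gene on the same strand with at least
#' 50% reciprocal overlap confirms that annotation; all others are novel.
#'
#' @param members Tibble from [filter_members()].
#' @param annotations Tibble as from [read_gff3()] (may be empty).
#' @param min_reciprocal Reciprocal-overlap fraction (default 0.5).
#' @return `members` with `status` ("confirms-annotated"/"novel") and
#'   `matched_gene` columns.
#' @export
reconcile_with_annotation <- function(members, annotations,
                                      min_reciprocal = 0.5) {
  status <- rep("novel", nrow(members))
  matched <- rep(NA_character_, nrow(members))
  if (nrow(annotations)) {
    for (i in seq_len(nrow(members))) {
      m <- members[i, ]
      for (j in seq_len(nrow(annotations))) {
        a <- annotations[j, ]
        if (a$seq_id != m$seq_id || a$strand != m$strand) next
        a0 <- gff_to_zero_based(a$start, a$end)
        ov <- min(m$g_end, a0$end) - max(m$g_start, a0$start)
        if (ov <= 0) next
        if (ov / (m$g_end - m$g_start) >= min_reciprocal &&
            ov / (a0$end - a0$start) >= min_reciprocal) {
          status[i] <- "confirms-annotated"
          matched[i] <- a$gene_id
          break
        }
      }
    }
  }
  dplyr::mutate(members, status = !!status, matched_gene = !!matched)
}

#' Full motif-anchored paralog scan of a genome
#'
#' Runs the whole detection strategy: six-frame translation of every
#' chromosome, anchor-motif location, window extension to the target
#' protein length, membership filtering by motif count, and reconciliation
#' against the annotation.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param motifs A `motif_set` (the full seed catalogue).
#' @param first_id,last_id Ids of the spatially first and last motifs of
#'   the seed architecture, used as anchors.
#' @param annotations Optional annotation tibble; default empty (all
#'   members novel).
#' @param offsets Window offsets, see [anchor_offsets()].
#' @inheritParams build_candidates
#' @inheritParams filter_members
#' @return Tibble of members with genomic coordinates (plus 1-based
#'   `start`/`end` columns), protein, motif counts and status.
#' @export
scan_genome <- function(genome, motifs, first_id, last_id,
                        annotations = NULL, target_len = 280,
                        offsets = c(first = 0, last = 0), min_motifs = 3,
                        min_length = 90, identity_threshold = 0.6) {
  first_motif <- motifs[[which(motif_ids(motifs) == first_id)]]
  last_motif <- motifs[[which(motif_ids(motifs) == last_id)]]
  members <- purrr::map_dfr(names(genome), function(sid) {
    tracks <- six_frame_translate(genome[[sid]], seq_id = sid)
    anchors <- find_anchors(tracks, first_motif, last_motif,
                            identity_threshold)
    cand <- build_candidates(anchors, tracks, target_len = target_len,
                             offsets = offsets, min_length = min_length)
    filter_members(cand, motifs, min_motifs, identity_threshold)
  })
  if (is.null(annotations)) {
    annotations <- tibble(gene_id = character(), seq_id = character(),
                          start = integer(), end = integer(),
                          strand = character())
  }
  members <- reconcile_with_annotation(members, annotations)
  dplyr::mutate(members,
                start = .data$g_start + 1L, end = .data$g_end) %>%
    dplyr::relocate("seq_id", "strand", "start", "end")
}

#' Write scan results to standard formats
#'
#' Emits `<prefix>_members.gff3` (gene features with the status in the
#' attributes), `<prefix>_proteins.fasta`, and `<prefix>_hits.tsv` (the
#' member table without sequences).
#'
#' @param members Tibble from [scan_genome()].
#' @param prefix Output path prefix.
#' @return The prefix, invisibly.
#' @export
write_members <- function(members, prefix) {
  ann <- dplyr::transmute(members,
                          gene_id = sprintf("candidate_%03d",
                                            seq_len(nrow(members))),
                          seq_id = .data$seq_id, start = .data$start,
                          end = .data$end, strand = .data$strand,
                          status = .data$status)
  write_gff3(ann, paste0(prefix, "_members.gff3"))
  write_fasta(setNames(members$protein, ann$gene_id),
              paste0(prefix, "_proteins.fasta"))
  readr::write_tsv(dplyr::select(members, -"protein"),
                   paste0(prefix, "_hits.tsv"), progress = FALSE)
  invisible(prefix)
}
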