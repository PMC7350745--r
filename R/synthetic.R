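#' Default conserved motif templates for the synthetic family
#'
#' Nine ordered amino-acid consensus templates with widths from 50 down to
#' 7 residues (average ~23), mirroring a family whose longest and shortest
#' conserved blocks span that range. Templates are fixed strings so that
#' generated families are reproducible.
#'
#' @return Character vector of 9 templates, named `T1`..`T9` in protein
#'   order (N- to C-terminal).
#' @export
default_motif_templates <- function() {
  c(T1 = "MEDLLSRFWGEKAPQTHVDNICYRAGSLKTFEMPWQHVRDASYGNLICKE",
    T2 = "WQRYCNDPAGHTKLMSVFIECAGHMWRTYK",
    T3 = "KHGFEDCAWRTYLMNPQSVIAGHECKDF",
    T4 = "PLMKIHGFEDCARNQSTVWYAEDGH",
    T5 = "DEQNHRKSTAGPVILMFWYCAG",
    T6 = "AVLIMFWPGSTCYNQDEH",
    T7 = "RKHDESTNQAVLIMF",
    T8 = "GPAVLIWYFMCS",
    T9 = "WYFHKRD")
}

#' Default promoter cis-element plant
#'
#' Three PLACE-style elements (a CAAT box, a Dof core, and a G-box) with
#' per-promoter plant counts. Counts are modest so that exact planting into
#' a 3-kb promoter is always feasible.
#'
#' @return A tibble with columns `name`, `iupac`, `count`.
#' @export
default_promoter_plant <- function() {
  tibble(name = c("CAATBOX1", "DOFCOREZM", "GBOXCORE"),
         iupac = c("CAAT", "AAAG", "CACGTG"),
         count = c(8L, 6L, 2L))
}

#' Specification of a synthetic tandem-duplicated family
#'
#' Describes the architecture of a single-chromosome tandem array of
#' single-exon paralogs whose translations share an ordered set of
#' conserved motifs. Defaults emulate the structure of the studied clade:
#' 18 members of ~280 residues carrying 9 ordered motifs, 12 of them
#' annotated, two truncated members (one missing its 4 N-terminal motifs,
#' one missing its 2 C-terminal motifs), and promoters of 3000 nt with
#' planted cis-elements at known counts.
#'
#' @param n_members Number of paralogs on the chromosome.
#' @param member_length Target full-length protein size in residues.
#' @param motif_templates Ordered named character vector of motif consensus
#'   templates (widths 7-50).
#' @param substitution_rate Per-residue probability that a motif residue is
#'   mutated in a given member, in `[0, 0.5]`.
#' @param truncations Named list mapping member index (as character) to the
#'   template indices that member loses; only leading or trailing runs are
#'   meaningful. `NULL` for no truncations.
#' @param intergenic_gap Random intergenic spacer length (nt) between the
#'   promoter+gene blocks.
#' @param strand_pattern Character vector of strands recycled over members.
#' @param n_annotated How many members receive GFF3 records; the rest are
#'   "unannotated" members the scan should discover.
#' @param promoter_plant Tibble (`name`, `iupac`, `count`) of elements
#'   planted in every promoter at exactly `count` forward-strand
#'   occurrences.
#' @param promoter_length Promoter length in nt.
#' @return A `family_spec` list.
#' @export
family_spec <- function(n_members = 18,
                        member_length = 280,
                        motif_templates = default_motif_templates(),
                        substitution_rate = 0.05,
                        truncations = list(`12` = 1:4, `14` = 8:9),
                        intergenic_gap = 500,
                        strand_pattern = c("+", "+", "-"),
                        n_annotated = 12,
                        promoter_plant = default_promoter_plant(),
                        promoter_length = 3000) {
  stopifnot(n_members >= 1, substitution_rate >= 0, substitution_rate <= 0.5,
            n_annotated <= n_members, n_annotated >= 0)
  w <- nchar(motif_templates)
  if (any(w < 7 | w > 50)) abort("motif template widths must lie in [7, 50]")
  validate_alphabet(setNames(motif_templates, names(motif_templates)),
                    "protein")
  if (!is.null(truncations)) {
    bad <- as.integer(names(truncations)) > n_members
    truncations <- truncations[!bad]
  }
  spec <- list(n_members = n_members, member_length = member_length,
               motif_templates = motif_templates,
               substitution_rate = substitution_rate,
               truncations = truncations %||% list(),
               intergenic_gap = intergenic_gap,
               strand_pattern = strand_pattern,
               n_annotated = n_annotated,
               promoter_plant = promoter_plant,
               promoter_length = promoter_length)
  structure(spec, class = "family_spec")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein <- function(n) {
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

mutate_protein <- function(x, rate) {
  if (rate == 0) return(x)
  ch <- chars(x)
  hit <- runif(length(ch)) < rate
  if (any(hit)) {
    ch[hit] <- vapply(ch[hit], function(a) sample(setdiff(AA20, a), 1),
                      character(1))
  }
  paste(ch, collapse = "")
}

codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

reverse_translate <- function(protein) {
  tab <- codon_table()
  ch <- chars(protein)
  codons <- vapply(ch, function(a) {
    opts <- tab[[a]]
    opts[sample.int(length(opts), 1)]
  }, character(1))
  paste(codons, collapse = "")
}

#' Generate a synthetic family genome with known ground truth
#'
#' Emits one chromosome carrying a tandem array of single-exon paralogs
#' whose translations contain the spec's motif templates in order, each
#' gene preceded (in transcription orientation) by a promoter containing
#' exactly the planted cis-element counts on its forward strand and no
#' other occurrences of those patterns. Minus-strand members are emitted
#' reverse-complemented. Only `n_annotated` members appear in the
#' annotation; the rest are the "unannotated paralogs" the scan stage must
#' discover. The generator is a pure function of `(spec, seed)`.
#'
#' At `substitution_rate == 0` the family is clonal: all full-length member
#' translations are identical. At positive rates motif blocks are mutated
#' copies of the shared templates while inter-motif spacers are drawn
#' independently per member, so only the planted motifs are conserved
#' across the family.
#'
#' @param spec A [family_spec()].
#' @param seed Integer seed.
#' @return A list with `genome` (named character vector, one chromosome
#'   `chr_sim`), `annotation` (tibble of annotated genes, 1-based
#'   inclusive), and `truth` (list: `members` tibble with coordinates,
#'   strands, proteins, annotation status and truncations; `promoters`
#'   tibble of planted element occurrences with TSS-relative positions;
#'   `elements` the plant spec).
#' @export
generate_family_genome <- function(spec, seed) {
  stopifnot(inherits(spec, "family_spec"))
  withr::with_seed(as.integer(seed), generate_family_genome_impl(spec))
}

generate_family_genome_impl <- function(spec) {
  n <- spec$n_members
  strands <- rep(spec$strand_pattern, length.out = n)
  annotated_idx <- if (spec$n_annotated > 0) {
    unique(round(seq(1, n, length.out = spec$n_annotated)))
  } else integer()

  # spacer budget for the full-length protein
  tw <- nchar(spec$motif_templates)
  k <- length(tw)
  budget <- spec$member_length - 1L - sum(tw)
  n_spacers <- k + 1L  # leader, k-1 linkers, trailer
  if (budget < n_spacers) {
    abort("member_length too small for the motif templates plus spacers")
  }
  spacer_len <- diff(floor(seq(0, budget, length.out = n_spacers + 1)))

  shared_spacers <- lapply(spacer_len, random_protein)  # used when rate == 0

  proteins <- character(n)
  kept_templates <- vector("list", n)
  for (i in seq_len(n)) {
    drop <- spec$truncations[[as.character(i)]] %||% integer()
    keep <- setdiff(seq_len(k), drop)
    kept_templates[[i]] <- keep
    spacers <- if (spec$substitution_rate == 0) {
      shared_spacers
    } else {
      lapply(spacer_len, random_protein)
    }
    pieces <- character(0)
    pieces <- c(pieces, spacers[[min(keep)]])
    for (j in keep) {
      pieces <- c(pieces,
                  mutate_protein(spec$motif_templates[[j]],
                                 spec$substitution_rate))
      if (j != max(keep)) pieces <- c(pieces, spacers[[j + 1L]])
    }
    pieces <- c(pieces, spacers[[n_spacers]])
    proteins[i] <- paste0("M", paste(pieces, collapse = ""))
  }

  promoters <- character(n)
  plant_rows <- vector("list", n)
  for (i in seq_len(n)) {
    pp <- plant_promoter(spec$promoter_length, spec$promoter_plant)
    promoters[i] <- pp$sequence
    if (nrow(pp$plants)) {
      pp$plants$member <- sprintf("member_%02d", i)
      plant_rows[[i]] <- pp$plants
    }
  }

  chrom_parts <- character(0)
  pos <- 0L  # 0-based running cursor
  members <- vector("list", n)
  for (i in seq_len(n)) {
    gap <- random_dna(spec$intergenic_gap)
    cds <- paste0(reverse_translate(proteins[i]), "TAA")
    if (strands[i] == "+") {
      block <- paste0(promoters[i], cds)
      gene_start0 <- pos + nchar(gap) + nchar(promoters[i])
    } else {
      block <- revcomp(paste0(promoters[i], cds))
      gene_start0 <- pos + nchar(gap)
    }
    gene_end0 <- gene_start0 + nchar(cds)  # half-open
    chrom_parts <- c(chrom_parts, gap, block)
    pos <- pos + nchar(gap) + nchar(block)
    members[[i]] <- tibble(
      member_id = sprintf("member_%02d", i),
      start = gene_start0 + 1L, end = gene_end0,  # 1-based inclusive
      strand = strands[i], protein = proteins[i],
      annotated = i %in% annotated_idx,
      templates = list(kept_templates[[i]])
    )
  }
  chrom_parts <- c(chrom_parts, random_dna(spec$intergenic_gap))
  genome <- setNames(paste(chrom_parts, collapse = ""), "chr_sim")
  members <- dplyr::bind_rows(members) %>%
    dplyr::mutate(seq_id = "chr_sim", .after = "member_id")

  annotation <- members %>%
    dplyr::filter(.data$annotated) %>%
    dplyr::transmute(gene_id = .data$member_id, seq_id = .data$seq_id,
                     start = .data$start, end = .data$end,
                     strand = .data$strand)

  truth <- list(members = members,
                promoters = dplyr::bind_rows(plant_rows),
                elements = spec$promoter_plant,
                spec = spec)
  list(genome = genome, annotation = annotation, truth = truth)
}

# Build one promoter: random background purged of every plant pattern,
# then exact plants inserted and the whole sequence re-verified so the
# forward-strand census of each pattern equals its planted count exactly.
plant_promoter <- function(len, plant, max_retries = 40L) {
  patterns <- plant$iupac
  for (try in seq_len(max_retries)) {
    seq <- random_dna(len)
    # choose non-overlapping plant slots with padding between them
    widths <- rep(nchar(plant$iupac), plant$count)
    names(widths) <- rep(plant$name, plant$count)
    pat_of_slot <- rep(plant$iupac, plant$count)
    need <- sum(widths + 10L)
    if (need > len) abort("promoter too short for the requested plants; use fewer/shorter elements or a longer promoter")
    ord <- sample(length(widths))
    widths <- widths[ord]; pat_of_slot <- pat_of_slot[ord]
    starts <- plant_slots(len, widths)
    if (is.null(starts)) next
    ch <- chars(seq)
    for (s in seq_along(starts)) {
      inst <- iupac_instance(pat_of_slot[s])
      ch[starts[s]:(starts[s] + nchar(inst) - 1L)] <- chars(inst)
    }
    planted_iv <- cbind(starts, starts + widths - 1L)
    seq2 <- paste(ch, collapse = "")
    seq2 <- purge_spurious(seq2, patterns, planted_iv, pat_of_slot)
    if (is.null(seq2)) next
    counts <- vapply(patterns, function(p) iupac_count_forward(seq2, p),
                     integer(1))
    if (all(counts == plant$count)) {
      plants <- tibble(
        element = names(widths),
        start_in_promoter = unname(starts),
        position = unname(starts) - len - 1L  # TSS-relative, in [-len, -1]
      ) %>% dplyr::arrange(.data$element, .data$start_in_promoter)
      return(list(sequence = seq2, plants = plants))
    }
  }
  abort("could not realize the promoter plant; try a longer promoter or fewer elements")
}

plant_slots <- function(len, widths, min_sep = 10L, max_tries = 200L) {
  for (t in seq_len(max_tries)) {
    starts <- sort(sample.int(len - max(widths) - 1L, length(widths)))
    ends <- starts + widths - 1L
    if (all(diff(starts) >= (widths[-length(widths)] + min_sep)) &&
        ends[length(ends)] <= len) {
      return(starts)
    }
  }
  NULL
}

iupac_instance <- function(pattern) {
  paste(vapply(chars(pattern), function(c) {
    opts <- IUPAC_SETS[[c]]
    opts[sample.int(length(opts), 1)]
  }, character(1)), collapse = "")
}

# mutate bases outside planted intervals until no unplanted match remains
purge_spurious <- function(seq, patterns, planted_iv, pat_of_slot,
                           max_iter = 300L) {
  ch <- chars(seq)
  in_plant <- rep(FALSE, length(ch))
  for (r in seq_len(nrow(planted_iv))) {
    in_plant[planted_iv[r, 1]:planted_iv[r, 2]] <- TRUE
  }
  planted_starts <- split(planted_iv[, 1], pat_of_slot)
  for (it in seq_len(max_iter)) {
    dirty <- FALSE
    for (p in patterns) {
      hits <- iupac_starts_forward(paste(ch, collapse = ""), p)
      spurious <- setdiff(hits, planted_starts[[p]] %||% integer())
      for (s in spurious) {
        span <- s:(s + nchar(p) - 1L)
        mutable <- span[!in_plant[span]]
        if (!length(mutable)) return(NULL)  # nested in a plant: give up
        j <- mutable[1]
        ch[j] <- sample(setdiff(c("A", "C", "G", "T"),
                                unlist(IUPAC_SETS[chars(p)[which(span == j)]])),
                        1)
        dirty <- TRUE
      }
    }
    if (!dirty) return(paste(ch, collapse = ""))
  }
  NULL
}

#' Generate expression series with one planted co-expression module
#'
#' Produces `n_series` independent gene-by-sample expression matrices in
#' which the genes of `module_genes` follow a shared latent profile per
#' series (expected pairwise correlation `module_correlation` on the log
#' scale) and all other genes are independent noise. Values are generated
#' on the log2 scale (mean 5, sd 2) and transformed to TPM-like positives
#' via `2^x - 1`, so [log2p1()] recovers the latent scale.
#'
#' @param module_genes Character vector of planted-module gene ids
#'   (typically the family plus a few extra "co-expressed" genes).
#' @param n_series Number of independent series.
#' @param n_genes Total gene universe size (module included).
#' @param n_samples Samples per series (>= 4).
#' @param module_correlation Target within-module pairwise correlation, in
#'   `(0, 1]`.
#' @param seed Integer seed; same seed reproduces the matrices exactly.
#' @return A list with `series` (list of numeric matrices, genes x
#'   samples) and `truth` (list with `module_genes`).
#' @export
generate_expression_series <- function(module_genes, n_series = 5,
                                       n_genes = 2000, n_samples = 12,
                                       module_correlation = 0.9, seed = 1) {
  if (length(module_genes) > n_genes) {
    abort("planted module larger than the gene universe")
  }
  stopifnot(n_samples >= 4, module_correlation > 0, module_correlation <= 1)
  n_bg <- n_genes - length(module_genes)
  gene_ids <- c(module_genes, sprintf("bg_%05d", seq_len(n_bg)))
  rho <- module_correlation
  series <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_series), function(s) {
      z <- rnorm(n_samples)
      lat <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples)
      is_mod <- gene_ids %in% module_genes
      lat[is_mod, ] <- sqrt(rho) * matrix(z, sum(is_mod), n_samples,
                                          byrow = TRUE) +
        sqrt(1 - rho) * lat[is_mod, , drop = FALSE]
      y <- 5 + 2 * lat
      m <- pmax(2^y - 1, 0)
      dimnames(m) <- list(gene_ids, sprintf("sample_%02d", seq_len(n_samples)))
      m
    })
  })
  names(series) <- sprintf("series_%d", seq_len(n_series))
  list(series = series, truth = list(module_genes = module_genes))
}

#' Write a generated family genome and its ground truth to disk
#'
#' Emits `<prefix>_genome.fasta`, `<prefix>_annotation.gff3` (annotated
#' members only), `<prefix>_members.tsv` (full truth, template lists
#' collapsed with `;`) and `<prefix>_promoter_plants.tsv`.
#'
#' @param sim Result of [generate_family_genome()].
#' @param prefix Output path prefix.
#' @return The prefix, invisibly.
#' @export
write_family_genome <- function(sim, prefix) {
  write_fasta(sim$genome, paste0(prefix, "_genome.fasta"))
  write_gff3(sim$annotation, paste0(prefix, "_annotation.gff3"))
  members <- dplyr::mutate(
    sim$truth$members,
    templates = vapply(.data$templates, paste, character(1),
                       collapse = ";"))
  readr::write_tsv(members, paste0(prefix, "_members.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$truth$promoters,
                   paste0(prefix, "_promoter_plants.tsv"),
                   progress = FALSE)
  invisible(prefix)
}
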