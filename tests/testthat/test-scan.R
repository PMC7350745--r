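test_that("six-frame translation follows the codon table on both strands", {
  tr <- six_frame_translate("ATGAAATAA")
  fwd0 <- tr[[1]]
  expect_equal(fwd0$protein, "MK*")
  rev_tracks <- six_frame_translate("TTACATCAT")
  expect_equal(rev_tracks[[4]]$protein, "MM*")  # revcomp = ATGATGTAA
  # reverse-strand residue 1 sits on the last codon in forward coordinates
  expect_equal(residue_interval(rev_tracks[[4]], 1, 1), c(6L, 9L))
  expect_equal(residue_interval(rev_tracks[[4]], 1, 3), c(0L, 9L))
})

test_that("all six tracks agree with an independent per-codon oracle", {
  withr::local_seed(41)
  s <- random_dna_str(300)
  tracks <- six_frame_translate(s)
  rc <- oracle_revcomp(s)
  for (tr in tracks) {
    src <- if (tr$strand == "+") s else rc
    f <- tr$frame
    ncod <- (nchar(src) - f) %/% 3
    codons <- substring(src, f + 1 + 3 * (0:(ncod - 1)),
                        f + 3 * (1:ncod))
    want <- paste(vapply(codons, function(cd) {
      aa <- seqinr::translate(strsplit(cd, "")[[1]])
      aa
    }, character(1)), collapse = "")
    expect_equal(tr$protein, want)
  }
  # N-containing codons translate to X
  trn <- six_frame_translate("ATGANATAA")
  expect_equal(trn[[1]]$protein, "MX*")
})

test_that("anchors are found for every planted member and map correctly", {
  g <- ref_family
  tracks <- six_frame_translate(g$genome[["chr_sim"]], seq_id = "chr_sim")
  fm <- ref_motifs[[which(motif_ids(ref_motifs) == ref_first)]]
  lm <- ref_motifs[[which(motif_ids(ref_motifs) == ref_last)]]
  anchors <- find_anchors(tracks, fm, lm)
  n <- nrow(g$truth$members)
  expect_gte(sum(anchors$anchor == "first"), n)
  expect_gte(sum(anchors$anchor == "last"), n)
  # each minus-strand anchor's genomic interval reverse-maps to its
  # residues: re-translating the interval recovers the track substring
  minus <- dplyr::filter(anchors, strand == "-")
  expect_gt(nrow(minus), 0)
  for (i in seq_len(min(nrow(minus), 4))) {
    a <- minus[i, ]
    sub <- substr(g$genome[["chr_sim"]], a$g_start + 1, a$g_end)
    prot <- as.character(Biostrings::translate(
      Biostrings::DNAString(revcomp(sub)), if.fuzzy.codon = "X"))
    tr <- tracks[[a$track]]
    expect_equal(prot, substr(tr$protein, a$res_start, a$res_end))
  }
})

test_that("an anchor-free genome yields no anchors", {
  withr::local_seed(43)
  s <- random_dna_str(6000)
  tracks <- six_frame_translate(s)
  fm <- ref_motifs[[which(motif_ids(ref_motifs) == ref_first)]]
  lm <- ref_motifs[[which(motif_ids(ref_motifs) == ref_last)]]
  expect_equal(nrow(find_anchors(tracks, fm, lm)), 0)
})

test_that("lone anchors extend to the target length in stop-free tracks", {
  m <- exact_motif("M1", "WQRYCNDPAG")
  withr::local_seed(47)
  prot <- paste0(random_protein_str(400), "WQRYCNDPAG",
                 random_protein_str(400))
  track <- list(seq_id = "t", strand = "+", frame = 0L, protein = prot,
                seq_len = 3L * nchar(prot))
  anchors <- find_anchors(list(track), m, exact_motif("M2", "YYYWWWYYYW"))
  expect_equal(nrow(anchors), 1)
  cand <- build_candidates(anchors, list(track), target_len = 280,
                           offsets = c(first = 20, last = 0))
  expect_equal(nchar(cand$protein), 280)
  expect_equal(cand$g_end - cand$g_start, 3L * 280L)

  # an anchor close to a stop codon is clipped, then discarded when the
  # stop-free remnant is shorter than min_length
  prot2 <- paste0(random_protein_str(30), "*", random_protein_str(10),
                  "WQRYCNDPAG", random_protein_str(20), "*",
                  random_protein_str(200))
  track2 <- list(seq_id = "t", strand = "+", frame = 0L, protein = prot2,
                 seq_len = 3L * nchar(prot2))
  anchors2 <- find_anchors(list(track2), m, exact_motif("M2", "YYYWWWYYYW"))
  cand2 <- build_candidates(anchors2, list(track2), target_len = 280,
                            offsets = c(first = 20, last = 0),
                            min_length = 90)
  expect_equal(nrow(cand2), 0)
  cand2b <- build_candidates(anchors2, list(track2), target_len = 280,
                             offsets = c(first = 20, last = 0),
                             min_length = 30)
  expect_equal(nrow(cand2b), 1)
  expect_equal(nchar(cand2b$protein), 40)  # the stop-free segment
})

test_that("paired anchors recover the planted protein exactly", {
  g <- ref_family
  members <- scan_genome(g$genome, ref_motifs, ref_first, ref_last,
                         annotations = g$annotation, offsets = ref_offsets)
  expect_equal(nrow(members), nrow(g$truth$members))
  expect_setequal(members$protein, g$truth$members$protein)
})

test_that("membership requires the minimum motif count", {
  consensi <- ref_spec$motif_templates[1:4]
  mots <- exact_motif_set(consensi)
  withr::local_seed(53)
  spacer <- function() random_protein_str(15)
  with3 <- paste0("M", spacer(), consensi[1], spacer(), consensi[2],
                  spacer(), consensi[3], spacer())
  with2 <- paste0("M", spacer(), consensi[1], spacer(), consensi[2],
                  spacer())
  cand <- tibble::tibble(
    seq_id = "c", strand = "+", frame = 0L,
    g_start = c(0L, 1000L), g_end = c(0L, 1000L) + 3L * nchar(c(with3, with2)),
    res_start = 1L, res_end = nchar(c(with3, with2)),
    protein = c(with3, with2))
  kept <- filter_members(cand, mots, min_motifs = 3)
  expect_equal(kept$protein, with3)
  expect_equal(kept$n_motifs, 3L)
})

test_that("overlapping windows over one member collapse to one call", {
  g <- ref_family
  tracks <- six_frame_translate(g$genome[["chr_sim"]], seq_id = "chr_sim")
  fm <- ref_motifs[[which(motif_ids(ref_motifs) == ref_first)]]
  lm <- ref_motifs[[which(motif_ids(ref_motifs) == ref_last)]]
  anchors <- find_anchors(tracks, fm, lm)
  cand <- build_candidates(anchors, tracks, offsets = ref_offsets)
  # duplicate every candidate, shifted, to force overlap resolution
  shifted <- dplyr::mutate(cand,
                           g_start = g_start + 30L, g_end = g_end + 30L,
                           res_start = res_start + 10L,
                           res_end = res_end + 10L,
                           protein = substr(protein, 11, nchar(protein)))
  both <- dplyr::bind_rows(cand, shifted)
  kept <- filter_members(both, ref_motifs, min_motifs = 3)
  expect_equal(nrow(kept), nrow(g$truth$members))
  # the higher-motif-count (full) windows win
  expect_setequal(kept$protein, cand$protein)
})

test_that("members confirm annotations or are flagged novel", {
  sp <- family_spec(n_members = 5, n_annotated = 3, truncations = NULL,
                    substitution_rate = 0.05, promoter_length = 800,
                    promoter_plant = default_promoter_plant()[1, ])
  g <- generate_family_genome(sp, seed = 7)
  members <- scan_genome(g$genome, ref_motifs, ref_first, ref_last,
                         annotations = g$annotation, offsets = ref_offsets)
  expect_equal(sum(members$status == "confirms-annotated"), 3)
  expect_equal(sum(members$status == "novel"), 2)
  all_novel <- reconcile_with_annotation(members,
                                         g$annotation[0, ])
  expect_true(all(all_novel$status == "novel"))
})

test_that("planted members are recovered perfectly across random families", {
  withr::local_seed(61)
  for (s in 1:3) {
    n <- sample(5:12, 1)
    novel <- sample(2:4, 1)
    sp <- family_spec(n_members = n, n_annotated = n - novel,
                      truncations = NULL,
                      substitution_rate = runif(1, 0, 0.10),
                      promoter_length = 600,
                      promoter_plant = default_promoter_plant()[1, ])
    g <- generate_family_genome(sp, seed = 100 + s)
    members <- scan_genome(g$genome, ref_motifs, ref_first, ref_last,
                           annotations = g$annotation,
                           offsets = ref_offsets)
    expect_equal(nrow(members), n)
    # every truth member matched by exactly one call at >= 50% overlap
    truth <- g$truth$members
    ov <- outer(seq_len(nrow(members)), seq_len(nrow(truth)),
                Vectorize(function(i, j) {
                  w <- min(members$end[i], truth$end[j]) -
                    max(members$start[i], truth$start[j]) + 1
                  w >= 0.5 * (truth$end[j] - truth$start[j] + 1) &&
                    members$strand[i] == truth$strand[j]
                }))
    expect_true(all(colSums(ov) == 1))
    expect_true(all(rowSums(ov) == 1))
    matched_status <- members$status[apply(ov, 2, which)]
    expect_equal(matched_status == "confirms-annotated", truth$annotated)
  }
})
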