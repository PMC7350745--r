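test_that("discovery recovers exactly the planted motif templates", {
  templates <- ref_spec$motif_templates
  expect_length(ref_motifs, length(templates))
  # every template is matched by one discovered consensus at high identity
  # and near-identical width
  hits <- vapply(templates, function(tpl) {
    best <- max(vapply(ref_motifs, function(m) {
      compare_motifs(m$consensus, tpl)
    }, numeric(1)))
    best
  }, numeric(1))
  expect_true(all(hits >= 80))
  widths <- sort(vapply(ref_motifs, `[[`, integer(1), "width"))
  expect_equal(widths, sort(unname(nchar(templates))), tolerance = 0.2)
})

test_that("identical sequences tile into maximally wide motifs", {
  seqs <- setNames(rep(paste(rep("ACDEFGHIKLMN", 10), collapse = ""), 4),
                   paste0("s", 1:4))
  aln <- progressive_msa(seqs, type = "protein")
  mots <- discover_motifs(aln)
  expect_equal(sum(vapply(mots, `[[`, integer(1), "width")), 120)
  expect_true(all(vapply(mots, `[[`, integer(1), "width") <= 50))
})

test_that("unrelated random sequences yield no motifs", {
  withr::local_seed(17)
  seqs <- setNames(vapply(1:10, function(i) random_protein_str(100),
                          character(1)), paste0("r", 1:10))
  aln <- progressive_msa(seqs, type = "protein")
  expect_warning(mots <- discover_motifs(aln), "threshold|block")
  expect_length(mots, 0)
})

test_that("scanning scores windows by log-odds with deterministic ties", {
  m <- exact_motif("M1", "WQRYCNDPAG")
  withr::local_seed(23)
  prot <- paste0(random_protein_str(40), "WQRYCNDPAG", random_protein_str(30))
  hit <- scan_protein(prot, m)
  expect_equal(hit$start, 41)
  expect_equal(hit$consensus_identity, 1.0)
  # brute-force window-score agreement on a protein of exactly motif width
  short <- paste(rev(strsplit("WQRYCNDPAG", "")[[1]]), collapse = "")
  hit2 <- scan_protein(short, m)
  sm <- log2(sweep(m$pfm, 2, m$background, "/"))
  ch <- strsplit(short, "")[[1]]
  expect_equal(hit2$logodds,
               sum(vapply(seq_along(ch), function(i) sm[i, ch[i]],
                          numeric(1))))
  # shorter-than-width protein is a no-hit, not a low-scoring hit
  expect_equal(nrow(scan_protein("MK", m)), 0)
})

test_that("consensus scan attains the per-column maximum score", {
  for (tpl in ref_spec$motif_templates[c(1, 5, 9)]) {
    m <- exact_motif("m", tpl)
    hit <- scan_protein(tpl, m)
    sm <- log2(sweep(m$pfm, 2, m$background, "/"))
    expect_equal(hit$logodds, sum(apply(sm, 1, max)))
    expect_equal(hit$consensus_identity, 1)
  }
})

test_that("shuffled members rarely pass the presence call", {
  motif <- ref_motifs[[which(motif_ids(ref_motifs) == ref_first)]]
  prot <- ref_proteins[[1]]
  withr::local_seed(29)
  fails <- vapply(1:200, function(i) {
    shuf <- paste(sample(strsplit(prot, "")[[1]]), collapse = "")
    hit <- call_presence(scan_protein(shuf, motif))
    !hit$present
  }, logical(1))
  expect_gte(mean(fails), 0.95)
})

test_that("presence calls follow the identity threshold and score sign", {
  base <- tibble::tibble(protein_id = "p", motif_id = "M1", start = 1L,
                         end = 10L, logodds = 5,
                         consensus_identity = c(1.0, 0.71, 0.2))
  called <- call_presence(base)
  expect_equal(called$present, c(TRUE, TRUE, FALSE))
  # positive identity but non-positive score is absent
  low <- dplyr::mutate(base[1, ], logodds = -1)
  expect_false(call_presence(low)$present)
})

test_that("architectures report planted motif order and truncations", {
  arch <- architecture(ref_proteins, ref_motifs)
  pm <- presence_matrix(arch, names(ref_proteins))
  expect_true(all(pm))
  # order along each protein follows the planted spatial order
  for (pid in names(ref_proteins)[1:5]) {
    sub <- dplyr::filter(arch, protein_id == pid)
    expect_equal(sub$motif_id, ref_spatial)
  }
  # a truncated member lacking the first four templates loses exactly the
  # motifs discovered at those positions
  tr_spec <- family_spec(n_members = 4, substitution_rate = 0.05,
                         truncations = list(`2` = 1:4), n_annotated = 2,
                         promoter_length = 600,
                         promoter_plant = default_promoter_plant()[1, ])
  tr <- generate_family_genome(tr_spec, seed = 3)
  tr_prot <- tr$truth$members$protein[2]
  hits <- architecture(c(m2 = tr_prot), ref_motifs)
  missing <- setdiff(ref_spatial, hits$motif_id)
  expect_setequal(missing, ref_spatial[1:4])

  empty <- architecture(character(), ref_motifs)
  expect_equal(nrow(empty), 0)
})

test_that("architecture ignores residues appended after the last motif", {
  prot <- ref_proteins[1]
  extended <- setNames(paste0(prot, "AAAAAAAAAAAAAAAAAAAA"), names(prot))
  a1 <- architecture(prot, ref_motifs)
  a2 <- architecture(extended, ref_motifs)
  expect_equal(as.data.frame(a1), as.data.frame(a2))
})

test_that("motif comparison equals exhaustive alignment identity", {
  m <- ref_motifs[[1]]
  expect_equal(compare_motifs(m, m), 100)
  withr::local_seed(37)
  sub <- default_submat("protein")
  for (i in 1:10) {
    a <- random_protein_str(6)
    b <- random_protein_str(6)
    got <- pairwise_align(a, b, type = "protein")
    oracle <- oracle_enumerate_alignments(a, b, sub, 10, 1)
    expect_equal(got$score, oracle$score)
    expect_true(any(abs(got$identity / 100 - oracle$identities) < 1e-9))
  }
})

test_that("motif sets serialize and reload losslessly", {
  prefix <- withr::local_tempfile()
  write_motifs(ref_motifs, prefix)
  back <- read_motifs(prefix)
  expect_equal(motif_ids(back), motif_ids(ref_motifs))
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$consensus, ref_motifs[[i]]$consensus)
    expect_equal(back[[i]]$pfm, ref_motifs[[i]]$pfm, tolerance = 1e-12)
  }
  td <- tidy(ref_motifs)
  expect_true(all(td$width >= 7 & td$width <= 50))
  expect_equal(glance(ref_motifs)$n_motifs, length(ref_motifs))
})
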