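test_that("promoter extraction uses the documented upstream arithmetic", {
  # plus strand: gene at 6,283,579 owns the 3000 bases ending at 6,283,578
  genome <- c(chr16 = strrep("A", 6284605))
  ann <- tibble::tibble(gene_id = "gene1", seq_id = "chr16",
                        start = 6283579L, end = 6284605L, strand = "+")
  reg <- extract_promoters(ann, genome, length = 3000)
  expect_equal(reg$start, 6280579L)
  expect_equal(reg$end, 6283578L)
  expect_equal(nchar(reg$sequence), 3000)
  expect_false(reg$clipped)
})

test_that("minus-strand promoters are the reverse complement downstream", {
  # 30-bp toy: gene on [5,10] minus strand; promoter = revcomp of [11,16]
  genome <- c(toy = "AACCGGTTAACCGGTTAACCGGTTAACCGG")
  ann <- tibble::tibble(gene_id = "g", seq_id = "toy", start = 5L,
                        end = 10L, strand = "-")
  reg <- extract_promoters(ann, genome, length = 6)
  expect_equal(reg$start, 11L)
  expect_equal(reg$end, 16L)
  expect_equal(reg$sequence, revcomp(substr(genome[["toy"]], 11, 16)))
})

test_that("regions at a chromosome edge are clipped and flagged", {
  genome <- c(c1 = strrep("ACGT", 200))
  ann <- tibble::tibble(gene_id = "edge", seq_id = "c1", start = 100L,
                        end = 150L, strand = "+")
  expect_warning(reg <- extract_promoters(ann, genome, length = 3000),
                 "clipped")
  expect_equal(nchar(reg$sequence), 99)
  expect_true(reg$clipped)
  expect_error(
    extract_promoters(
      tibble::tibble(gene_id = "g", seq_id = "nope", start = 10L,
                     end = 20L, strand = "+"), genome),
    "absent")
})

test_that("element scanning counts overlapping IUPAC matches", {
  reg <- tibble::tibble(gene_id = "p1", sequence = "GCAATCAATG")
  pat <- tibble::tibble(name = "CAATBOX1", iupac = "CAAT")
  cen <- scan_elements(reg, pat, strands = "forward")
  expect_equal(nrow(cen), 2)
  expect_equal(cen$position, c(-9L, -5L))
  # overlapping occurrences: AAAA twice in AAAAA
  reg2 <- tibble::tibble(gene_id = "p", sequence = "AAAAA")
  cen2 <- scan_elements(reg2, tibble::tibble(name = "A4", iupac = "AAAA"),
                        strands = "forward")
  expect_equal(nrow(cen2), 2)
  cen2b <- scan_elements(reg2, tibble::tibble(name = "A4", iupac = "AAAA"),
                         strands = "forward", overlapping = FALSE)
  expect_equal(nrow(cen2b), 1)
  expect_error(
    scan_elements(reg, tibble::tibble(name = "bad", iupac = "CAQT")),
    "invalid IUPAC code 'Q' in pattern 'bad'")
})

test_that("IUPAC counts equal an exhaustive regex oracle on both strands", {
  withr::local_seed(89)
  pats <- tibble::tibble(name = c("CAATBOX1", "WBOX", "GBOX", "MYBCORE"),
                         iupac = c("CAAT", "TTGACY", "CACGTG", "YAACKG"))
  for (i in 1:20) {
    seq <- random_dna_str(3000)
    reg <- tibble::tibble(gene_id = "p", sequence = seq)
    cen <- scan_elements(reg, pats, strands = "both")
    for (k in seq_len(nrow(pats))) {
      pat <- pats$iupac[k]
      fwd <- length(oracle_iupac_starts(seq, pat))
      # palindromic patterns are counted once per site by convention
      rev <- if (oracle_revcomp(pat) == pat) 0L else
        length(oracle_iupac_starts(seq, oracle_revcomp(pat)))
      got <- sum(cen$element == pats$name[k])
      expect_equal(got, fwd + rev)
    }
  }
})

test_that("palindromic patterns count once per site in both-strand mode", {
  reg <- tibble::tibble(gene_id = "p", sequence = "TTCACGTGTT")
  cen <- scan_elements(reg, tibble::tibble(name = "GBOX", iupac = "CACGTG"),
                       strands = "both")
  expect_equal(nrow(cen), 1)
})

test_that("strand-swapped scans give identical totals", {
  withr::local_seed(97)
  seq <- random_dna_str(2000)
  pat <- tibble::tibble(name = "WBOX", iupac = "TTGACY")
  a <- scan_elements(tibble::tibble(gene_id = "p", sequence = seq), pat)
  b <- scan_elements(
    tibble::tibble(gene_id = "p", sequence = revcomp(seq)), pat)
  expect_equal(nrow(a), nrow(b))
})

test_that("shared and private elements are classified exactly", {
  # deterministic promoters on a T background
  mk <- function(...) paste0(strrep("T", 50),
                             paste(c(...), collapse = strrep("T", 50)),
                             strrep("T", 50))
  regions <- tibble::tibble(
    gene_id = c("p1", "p2", "p3"),
    sequence = c(mk("CAAT", "CACGTG", "AAAG"),
                 mk("CAAT", "CACGTG"),
                 mk("CAAT", "GGATCC")))
  pats <- tibble::tibble(
    name = c("CAATBOX1", "GBOX", "DOF", "BAMHI"),
    iupac = c("CAAT", "CACGTG", "AAAG", "GGATCC"))
  cen <- scan_elements(regions, pats, strands = "forward")
  expect_equal(elements_in_all(cen), "CAATBOX1")
  expect_equal(unique_elements(cen, "p1"), "DOF")
  expect_equal(unique_elements(cen, "p3"), "BAMHI")
  expect_equal(unique_elements(cen, "p2"), character(0))
  expect_error(unique_elements(cen, "p9"), "unknown promoter")
  # single promoter: everything it contains is "in all"
  solo <- scan_elements(regions[1, ], pats, strands = "forward")
  expect_setequal(elements_in_all(solo), c("CAATBOX1", "GBOX", "DOF"))
})

test_that("promoter identity reuses the alignment machinery", {
  regs <- tibble::tibble(gene_id = c("a", "b"),
                         sequence = c("ACGTACGTACGTACGTAAAA",
                                      "ACGTACGTACGTACGTAAAA"))
  idm <- promoter_identity(regs)
  expect_equal(unclass(idm)[1, 2], 100)
  withr::local_seed(101)
  regs2 <- tibble::tibble(gene_id = c("a", "b"),
                          sequence = c(random_dna_str(300),
                                       random_dna_str(300)))
  idm2 <- promoter_identity(regs2)
  pw <- pairwise_align(regs2$sequence[1], regs2$sequence[2], type = "dna")
  expect_equal(unclass(idm2)[1, 2], pw$identity)
})
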