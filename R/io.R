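#' Read a FASTA file as a validated named character vector
#'
#' Loads a multi-record FASTA file, upper-casing all characters (soft-masked
#' lower-case bases are not tracked) and taking record ids from the first
#' whitespace-delimited token of each header. Records are validated against
#' the requested alphabet: `"nucleotide"` allows `A C G T N`, `"protein"`
#' allows the 20 standard residues plus `X`.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @return A named character vector of upper-case sequences, one element per
#'   record. Names are record ids and are guaranteed unique.
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate FASTA id: ", ids[duplicated(ids)][1]))
  }
  if (any(nchar(seqs) == 0L)) {
    abort(paste0("empty sequence for record: ", ids[nchar(seqs) == 0L][1]))
  }
  names(seqs) <- ids
  validate_alphabet(seqs, alphabet)
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

ALPHABETS <- list(
  nucleotide = c("A", "C", "G", "T", "N"),
  protein = c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
              "M", "F", "P", "S", "T", "W", "Y", "V", "X")
)

validate_alphabet <- function(seqs, alphabet) {
  allowed <- ALPHABETS[[alphabet]]
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[[i]], "")[[1]]
    bad <- which(!(ch %in% allowed))
    if (length(bad)) {
      abort(sprintf("invalid %s character '%s' in record '%s' at position %d",
                    alphabet, ch[bad[1]], names(seqs)[i], bad[1]))
    }
  }
  invisible(seqs)
}

#' Read gene annotations from GFF3
#'
#' Reads features of type `gene` from a GFF3 file into a tibble. Coordinates
#' stay 1-based inclusive, exactly as in the file; use
#' [gff_to_zero_based()] for the package's internal half-open convention.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `gene_id`, `seq_id`, `start`, `end`
#'   (1-based inclusive) and `strand` (`"+"` or `"-"`).
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (length(readLines(path, warn = FALSE)) == 0L ||
      all(grepl("^#|^\\s*$", readLines(path, warn = FALSE)))) {
    return(tibble(gene_id = character(), seq_id = character(),
                  start = integer(), end = integer(), strand = character()))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  if (length(gr) == 0L) {
    return(tibble(gene_id = character(), seq_id = character(),
                  start = integer(), end = integer(), strand = character()))
  }
  ids <- as.character(gr$ID)
  if (any(is.na(ids) | ids == "")) abort("gene feature without an ID attribute")
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate gene ID: ", ids[duplicated(ids)][1]))
  }
  ann <- tibble(
    gene_id = ids,
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  if (any(!ann$strand %in% c("+", "-"))) {
    abort("gene feature with missing or unknown strand")
  }
  if (any(ann$start > ann$end)) abort("gene feature with start > end")
  ann
}

#' Write gene annotations to GFF3
#'
#' @param ann Tibble as returned by [read_gff3()]; an optional `status`
#'   column is written into the attributes.
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(ann, path, source = "cladescan") {
  gr <- GenomicRanges::GRanges(
    seqnames = ann$seq_id,
    ranges = IRanges::IRanges(start = ann$start, end = ann$end),
    strand = ann$strand
  )
  gr$source <- source
  gr$type <- "gene"
  gr$ID <- ann$gene_id
  if ("status" %in% names(ann)) gr$status <- ann$status
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids. All
#' values must be non-negative and finite; row and column ids unique.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix with gene rownames and sample colnames.
#' @export
read_matrix <- function(path) {
  # values are read as text and converted with strtod so that decimal
  # representations round-trip to the identical double
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE, name_repair = "minimal")
  if (ncol(df) < 2L) abort("matrix file needs an id column plus data columns")
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate gene id: ", ids[duplicated(ids)][1]))
  }
  if (anyDuplicated(names(df)[-1])) abort("duplicate sample id in header")
  m <- suppressWarnings(
    vapply(df[-1], function(col) as.numeric(col), numeric(nrow(df))))
  if (nrow(df) == 1L) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(df)[-1]))
  rownames(m) <- ids
  if (any(!is.finite(m))) abort("missing or non-numeric value in matrix")
  if (any(m < 0)) abort("negative value in expression matrix")
  m
}

#' Write a gene-by-sample matrix to TSV
#'
#' @param m Numeric matrix with rownames and colnames.
#' @param path Output path.
#' @param id_col Name for the id column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, id_col = "gene_id") {
  df <- as_tibble(m, rownames = id_col)
  # %.17g guarantees the decimal text reads back to the identical double
  df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric),
                                        ~sprintf("%.17g", .x)))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Convert GFF3 1-based inclusive coordinates to 0-based half-open
#'
#' The package does all interval arithmetic in 0-based half-open
#' coordinates; GFF3 I/O converts at the boundary. These two helpers are an
#' exact bijection.
#'
#' @param start,end 1-based inclusive coordinates.
#' @return A list with `start` (0-based) and `end` (exclusive).
#' @export
gff_to_zero_based <- function(start, end) {
  list(start = start - 1L, end = end)
}

#' @rdname gff_to_zero_based
#' @param start0,end0 0-based half-open coordinates.
#' @export
zero_based_to_gff <- function(start0, end0) {
  list(start = start0 + 1L, end = end0)
}

#' Reverse-complement a nucleotide string
#'
#' @param x Character vector of nucleotide strings (A/C/G/T/N and IUPAC
#'   degenerate codes are supported).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
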