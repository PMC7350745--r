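# Independent oracles used across the suite. These deliberately share no
# code with the package internals they check.

# Affine-gap global alignment score by the O(n*m*gaplen) recursion:
# H[i,j] = max(diag, best gap of any explicit length k).
oracle_align_score <- function(a, b, submat, open, ext) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  H <- matrix(-Inf, n + 1, m + 1)
  H[1, 1] <- 0
  for (j in seq_len(m)) H[1, j + 1] <- -(open + j * ext)
  for (i in seq_len(n)) H[i + 1, 1] <- -(open + i * ext)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      best <- H[i, j] + submat[ca[i], cb[j]]
      for (k in seq_len(i)) {
        best <- max(best, H[i - k + 1, j + 1] - (open + k * ext))
      }
      for (k in seq_len(j)) {
        best <- max(best, H[i + 1, j - k + 1] - (open + k * ext))
      }
      H[i + 1, j + 1] <- best
    }
  }
  H[n + 1, m + 1]
}

# Enumerate every global alignment of two short strings, applying affine
# gap costs along the way; returns the optimal score and the identities
# (identical cols / total cols) attained by optimal alignments.
oracle_enumerate_alignments <- function(a, b, submat, open, ext) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  best <- new.env()
  best$score <- -Inf
  best$identities <- numeric()
  rec <- function(i, j, score, state, matches, cols) {
    if (i > length(ca) && j > length(cb)) {
      if (score > best$score + 1e-9) {
        best$score <- score
        best$identities <- matches / cols
      } else if (abs(score - best$score) <= 1e-9) {
        best$identities <- c(best$identities, matches / cols)
      }
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb)) {
      rec(i + 1, j + 1, score + submat[ca[i], cb[j]], 0,
          matches + (ca[i] == cb[j]), cols + 1)
    }
    if (i <= length(ca)) {
      pen <- if (state == 2) ext else open + ext
      rec(i + 1, j, score - pen, 2, matches, cols + 1)
    }
    if (j <= length(cb)) {
      pen <- if (state == 1) ext else open + ext
      rec(i, j + 1, score - pen, 1, matches, cols + 1)
    }
  }
  rec(1, 1, 0, 0, 0, 0)
  list(score = best$score, identities = unique(best$identities))
}

# Topological overlap by the literal triple loop.
oracle_tom <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { out[i, j] <- 1; next }
      s <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) s <- s + a[i, u] * a[u, j]
      }
      out[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  dimnames(out) <- dimnames(a)
  out
}

# IUPAC occurrence counting through PCRE lookahead regexes (overlapping
# matches), fully independent of Biostrings.
IUPAC_REGEX <- c(A = "A", C = "C", G = "G", T = "T",
                 R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
                 K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
                 H = "[ACT]", V = "[ACG]", N = "[ACGT]")

iupac_to_regex <- function(pattern) {
  paste(IUPAC_REGEX[strsplit(pattern, "")[[1]]], collapse = "")
}

oracle_iupac_starts <- function(seq, pattern) {
  rx <- paste0("(?=", iupac_to_regex(pattern), ")")
  m <- gregexpr(rx, seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer() else as.integer(m)
}

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", V = "B", D = "H", H = "D")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# Sum-of-pairs score of a multiple alignment under linear gap costs
# (gap-gap pair columns score 0).
sp_score_linear <- function(rows, submat, gapcost) {
  m <- do.call(rbind, lapply(rows, function(r) strsplit(r, "")[[1]]))
  total <- 0
  n <- nrow(m)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    for (col in seq_len(ncol(m))) {
      a <- m[i, col]; b <- m[j, col]
      if (a == "-" && b == "-") next
      total <- total + if (a == "-" || b == "-") -gapcost else submat[a, b]
    }
  }
  total
}

# Exhaustive three-way alignment (linear gaps, sum-of-pairs objective).
oracle_msa3_score <- function(a, b, c, submat, gapcost) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  cc <- strsplit(c, "")[[1]]
  la <- length(ca); lb <- length(cb); lc <- length(cc)
  H <- array(-Inf, dim = c(la + 1, lb + 1, lc + 1))
  H[1, 1, 1] <- 0
  pair <- function(x, y) {
    if (is.na(x) && is.na(y)) 0
    else if (is.na(x) || is.na(y)) -gapcost
    else submat[x, y]
  }
  for (i in 0:la) for (j in 0:lb) for (k in 0:lc) {
    if (i + j + k == 0) next
    cand <- -Inf
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      if (di + dj + dk == 0) next
      pi <- i - di; pj <- j - dj; pk <- k - dk
      if (pi < 0 || pj < 0 || pk < 0) next
      prev <- H[pi + 1, pj + 1, pk + 1]
      if (!is.finite(prev)) next
      xa <- if (di == 1) ca[i] else NA
      xb <- if (dj == 1) cb[j] else NA
      xc <- if (dk == 1) cc[k] else NA
      sc <- prev + pair(xa, xb) + pair(xa, xc) + pair(xb, xc)
      cand <- max(cand, sc)
    }
    H[i + 1, j + 1, k + 1] <- cand
  }
  H[la + 1, lb + 1, lc + 1]
}

random_protein_str <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               n, replace = TRUE), collapse = "")
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# exact-consensus motif model (uniform background): handy fixture
exact_motif <- function(id, consensus) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")
  ch <- strsplit(consensus, "")[[1]]
  pfm <- matrix(0.001 / 19, length(ch), 20, dimnames = list(NULL, aa))
  for (i in seq_along(ch)) pfm[i, ch[i]] <- 0.999
  pfm <- pfm / rowSums(pfm)
  motif_model(id, pfm)
}

exact_motif_set <- function(consensi) {
  structure(purrr::imap(unname(consensi),
                        ~exact_motif(paste0("M", .y), .x)),
            class = "motif_set")
}
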