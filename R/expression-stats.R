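#' log2(x + 1) transform
#'
#' @param m Non-negative gene-by-sample matrix.
#' @return The transformed matrix.
#' @export
log2p1 <- function(m) {
  if (any(m < 0)) abort("log2p1 requires non-negative values")
  log2(m + 1)
}

#' Per-gene Z-scores
#'
#' Centers and scales each row to mean 0, sd 1 (sample sd, denominator
#' n - 1). Constant rows cannot be scaled; they are emitted as zeros and
#' recorded in the `flagged_constant` attribute.
#'
#' @param m Gene-by-sample matrix with >= 2 samples.
#' @return Matrix of row Z-scores, with attribute `flagged_constant`.
#' @export
zscore_per_gene <- function(m) {
  if (ncol(m) < 2) abort("need at least 2 samples to compute Z-scores")
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  flagged <- rownames(m)[s == 0]
  s[s == 0] <- 1
  z <- (m - mu) / s
  z[flagged, ] <- 0
  attr(z, "flagged_constant") <- flagged
  z
}

#' Expression dominance of one clade member over the rest
#'
#' For each series, the ratio of the focal gene's mean expression (over
#' samples) to the mean expression of all other clade members pooled over
#' samples and genes, computed on the raw (untransformed) scale. The
#' aggregate is the arithmetic mean of the per-series ratios; a pooled
#' variant (total focal mean over total other-member mean across all
#' series) is also reported.
#'
#' @param series List of gene-by-sample matrices (raw scale), or a single
#'   matrix.
#' @param focal The focal gene id (must belong to `clade`).
#' @param clade Character vector of clade member ids.
#' @return A list: `per_series` tibble (`series`, `ratio`), `mean_ratio`,
#'   and `pooled_ratio`. Series with a zero denominator are flagged
#'   undefined (NA) and excluded from the aggregate with a warning.
#' @export
fold_dominance <- function(series, focal, clade) {
  if (!focal %in% clade) abort("focal gene must be a clade member")
  if (is.matrix(series)) series <- list(series_1 = series)
  if (is.null(names(series))) {
    names(series) <- sprintf("series_%d", seq_along(series))
  }
  others <- setdiff(clade, focal)
  per <- purrr::map_dfr(names(series), function(sn) {
    m <- series[[sn]]
    missing <- setdiff(clade, rownames(m))
    if (length(missing)) {
      abort(paste0("clade gene absent from series ", sn, ": ", missing[1]))
    }
    num <- mean(m[focal, ])
    den <- mean(m[others, , drop = FALSE])
    tibble(series = sn, focal_mean = num, others_mean = den,
           ratio = if (den == 0) NA_real_ else num / den)
  })
  if (any(is.na(per$ratio))) {
    warn("series with zero clade-mean expression excluded from the aggregate")
  }
  pooled_den <- mean(per$others_mean)
  list(per_series = dplyr::select(per, "series", "ratio"),
       mean_ratio = mean(per$ratio, na.rm = TRUE),
       pooled_ratio = if (pooled_den == 0) NA_real_ else
         mean(per$focal_mean) / pooled_den)
}

#' Per-gene differential-expression frequency across contrasts
#'
#' Counts, for each gene of interest, the number of contrasts whose DEG
#' set contains it.
#'
#' @param degs Named list of character vectors: one DEG id set per
#'   contrast (names are contrast labels, must be unique).
#' @param genes Character vector of genes to tabulate.
#' @return Tibble (`gene`, `n_contrasts`) sorted by descending count,
#'   ties by id.
#' @export
deg_frequency <- function(degs, genes) {
  if (anyDuplicated(names(degs))) abort("contrast labels must be unique")
  counts <- vapply(genes, function(g) {
    sum(vapply(degs, function(s) g %in% s, logical(1)))
  }, integer(1))
  tibble(gene = genes, n_contrasts = unname(counts)) %>%
    dplyr::arrange(dplyr::desc(.data$n_contrasts), .data$gene)
}

#' Z-score heatmap of clade expression
#'
#' log2(x+1) transforms, Z-scores per gene, and draws the standard
#' gene-by-sample heatmap.
#'
#' @param m Gene-by-sample matrix (raw scale).
#' @param genes Optional subset/order of genes to show.
#' @return A ggplot object.
#' @export
plot_expression_heatmap <- function(m, genes = NULL) {
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  z <- zscore_per_gene(log2p1(m))
  df <- as_tibble(as.table(z), .name_repair = "minimal") %>%
    setNames(c("gene", "sample", "z")) %>%
    as_tibble()
  ggplot2::ggplot(df, ggplot2::aes(.data$sample, .data$gene,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", name = "Z") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Read differential-expression gene sets from TSV
#'
#' Expects two columns, `contrast` and `gene`; each contrast's rows form
#' its DEG id set.
#'
#' @param path Path to a TSV file.
#' @return Named list of character vectors, one per contrast.
#' @export
read_deg_sets <- function(path) {
  df <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  if (!all(c("contrast", "gene") %in% names(df))) {
    abort("DEG table needs 'contrast' and 'gene' columns")
  }
  split(df$gene, df$contrast)
}
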