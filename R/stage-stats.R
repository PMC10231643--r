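# Shared statistics: PSI, group contrasts, Ward clustering, 2x2 chi-square
# and cell-type signature scoring.

#' Percent spliced in (PSI) per cassette exon
#'
#' For each internal exon, inclusion reads are junction reads joining the
#' exon to either neighbour, exclusion reads are junction reads joining the
#' two neighbours directly; `PSI = inclusion / (inclusion + exclusion)`,
#' missing when the denominator is zero. First exons are flagged
#' (`alt_first_exon`) and excluded from PSI, since alternative first exons
#' reflect transcription-start choice rather than splicing.
#'
#' @param placements A `read_placements` tibble (one sample).
#' @param models A [gene_models] object.
#' @param sample_id Sample label for the output.
#' @return Tibble with `exon_id` (`"<transcript>:E<genomic index>"`),
#'   `sample_id`, `inclusion_reads`, `exclusion_reads`, `PSI`,
#'   `alt_first_exon`. Exons without two neighbours are skipped.
#' @export
compute_psi <- function(placements, models, sample_id = NULL) {
  stopifnot(inherits(models, "gene_models"))
  if (is.null(sample_id)) {
    sample_id <- if (nrow(placements) > 0) placements$sample_id[1] else NA_character_
  }
  juncs <- splice_junctions(placements)
  jc <- juncs |>
    dplyr::count(.data$chrom, .data$junc_start, .data$junc_end, name = "n")
  jget <- function(chrom, a, b) {
    hit <- jc$n[jc$chrom == chrom & jc$junc_start == a & jc$junc_end == b]
    if (length(hit) == 0) 0L else hit[1]
  }
  rows <- list()
  for (tx in unique(models$exons$transcript_id)) {
    ex <- models$exons[models$exons$transcript_id == tx, ]
    ex <- ex[order(ex$start), ]
    n <- nrow(ex)
    if (n < 3) next
    for (k in 2:(n - 1)) {
      incl <- jget(ex$chrom[1], ex$end[k - 1], ex$start[k]) +
        jget(ex$chrom[1], ex$end[k], ex$start[k + 1])
      excl <- jget(ex$chrom[1], ex$end[k - 1], ex$start[k + 1])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        exon_id = sprintf("%s:E%d", tx, k), sample_id = sample_id,
        inclusion_reads = incl, exclusion_reads = excl,
        PSI = if (incl + excl > 0) incl / (incl + excl) else NA_real_,
        alt_first_exon = FALSE
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Contrast two sample groups feature by feature
#'
#' Fold change is the ratio of group means after adding `pseudocount`;
#' the p-value comes from a two-sided Welch t-test on log2-transformed
#' values; BH-adjusted values are reported alongside. The `regulated` flag
#' follows the screening rule: fold change above `fc_threshold` in either
#' direction AND raw p below `p_threshold`.
#'
#' @param values Numeric feature x sample matrix (rownames = feature ids).
#' @param low_samples,high_samples Column names of the two groups (>= 2
#'   samples each).
#' @param pseudocount Added before log/ratio (default 0.5).
#' @param fc_threshold,p_threshold Screening rule (defaults 1.5 and 0.05).
#' @return Tibble with `feature_id`, `fold_change`, `log2fc`, `p_value`,
#'   `fdr`, `regulated`.
#' @export
contrast_groups <- function(values, low_samples, high_samples,
                            pseudocount = 0.5, fc_threshold = 1.5,
                            p_threshold = 0.05) {
  stopifnot(
    length(low_samples) >= 2, length(high_samples) >= 2,
    all(c(low_samples, high_samples) %in% colnames(values))
  )
  values <- as.matrix(values)
  lo <- values[, low_samples, drop = FALSE] + pseudocount
  hi <- values[, high_samples, drop = FALSE] + pseudocount
  fc <- rowMeans(hi) / rowMeans(lo)
  p <- vapply(seq_len(nrow(values)), function(i) {
    x <- log2(lo[i, ])
    y <- log2(hi[i, ])
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      return(1)
    }
    tryCatch(stats::t.test(y, x)$p.value, error = function(e) 1)
  }, numeric(1))
  tibble::tibble(
    feature_id = rownames(values),
    fold_change = fc,
    log2fc = log2(fc),
    p_value = p,
    fdr = stats::p.adjust(p, method = "BH"),
    regulated = (fc > fc_threshold | fc < 1 / fc_threshold) & p < p_threshold
  )
}

#' Ward clustering of samples
#'
#' Agglomerative clustering of the sample columns using Euclidean distance
#' and the Ward minimum-variance criterion (`hclust` method `ward.D2`, the
#' variant operating on unsquared distances that minimizes within-cluster
#' variance). Missing values are imputed to the feature mean.
#'
#' @param values Numeric feature x sample matrix.
#' @return List with `hclust` (the tree) and `order` (leaf sample names,
#'   left to right, after deterministic seriation: leaves are rotated so
#'   that mean expression increases across the dendrogram where the tree
#'   allows).
#' @export
cluster_samples <- function(values) {
  if (ncol(values) < 2) stop("need at least 2 samples to cluster")
  m <- as.matrix(values)
  for (i in seq_len(nrow(m))) {
    miss <- is.na(m[i, ])
    if (any(miss)) m[i, miss] <- mean(m[i, !miss])
  }
  hc <- stats::hclust(stats::dist(t(m), method = "euclidean"), method = "ward.D2")
  dend <- stats::reorder(stats::as.dendrogram(hc), colMeans(m), agglo.FUN = mean)
  list(hclust = hc, order = labels(dend))
}

#' Pearson chi-square on a 2x2 table
#'
#' @param a,b,c,d Counts, row-wise: `rbind(c(a, b), c(c, d))`. All margins
#'   must be positive.
#' @param correct Apply Yates' continuity correction (default `TRUE`,
#'   matching R's `chisq.test` default used in the original screening).
#' @return List of class `chi2_2x2` with `table`, `chi2`, `p`, `log10_p`
#'   (computed in log space, so p-values far below double underflow are
#'   still exact).
#' @export
chi2_2x2 <- function(a, b, c, d, correct = TRUE) {
  m <- rbind(c(a, b), c(c, d))
  if (any(m < 0)) stop("counts must be non-negative")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) stop("zero margin")
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  dev <- abs(m - E)
  if (correct) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / E)
  log_p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE, log.p = TRUE)
  structure(
    list(
      table = m, chi2 = chi2, p = exp(log_p), log10_p = log_p / log(10),
      correct = correct
    ),
    class = "chi2_2x2"
  )
}

#' @export
print.chi2_2x2 <- function(x, ...) {
  cat("2x2 chi-square: X2 =", format(x$chi2, digits = 6),
    " log10(p) =", format(x$log10_p, digits = 6), "\n")
  invisible(x)
}

#' Cell-type signature scores
#'
#' Per-gene z-scores (across samples) averaged over the genes of each
#' signature. Genes with zero variance contribute a z-score of 0.
#'
#' @param expression Numeric gene x sample matrix (rownames = gene ids).
#' @param signatures Named list: cell type -> character vector of gene ids.
#' @return Cell-type x sample score matrix.
#' @export
signature_score <- function(expression, signatures) {
  m <- as.matrix(expression)
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  z <- (m - mu) / ifelse(sdv == 0, 1, sdv)
  z[sdv == 0, ] <- 0
  out <- matrix(NA_real_, length(signatures), ncol(m),
    dimnames = list(names(signatures), colnames(m))
  )
  for (ct in names(signatures)) {
    genes <- intersect(signatures[[ct]], rownames(m))
    if (length(genes) == 0) stop("no signature genes present for cell type: ", ct)
    out[ct, ] <- colMeans(z[genes, , drop = FALSE])
  }
  out
}
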