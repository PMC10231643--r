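# Back-splice junction (BSJ) detection, circRNA quantification against the
# linear transcript, stage-regulated calling and abundance ranking.

#' Detect back-splice junctions from split-read placements
#'
#' A read supports a BSJ when it has two segments whose genomic order is
#' inverted relative to query order (the supplementary-pair signature of a
#' circular junction), each segment is at least `min_seg` bases, and the
#' outer segment ends coincide with annotated splice sites within `tol`
#' bases: the genomically first segment starts at an exon start (the
#' acceptor) and the genomically last segment ends at an exon end (the
#' donor). Junctions are keyed by `(chrom, acceptor, donor)` snapped to the
#' annotation, and reported with at least `min_support` supporting reads
#' across samples.
#'
#' @param placements A `read_placements` tibble (may pool samples; per-sample
#'   counts are kept via `sample_id`).
#' @param models A [gene_models] object.
#' @param tol Splice-site snap tolerance in bp (default 2).
#' @param min_seg Minimum segment length (default 15).
#' @param min_support Minimum supporting reads per BSJ (default 2).
#' @return Tibble with `bsj_id` (`chrom:acceptor|donor`), `chrom`,
#'   `bsj_start` (acceptor), `bsj_end` (donor), `gene_id`, `sample_id`,
#'   `count`. Each read supports at most one BSJ.
#' @export
detect_bsj <- function(placements, models, tol = 2L, min_seg = 15L,
                       min_support = 2L) {
  cand <- placements[placements$is_supplementary_pair, ]
  if (nrow(cand) == 0) {
    return(tibble::tibble(
      bsj_id = character(), chrom = character(), bsj_start = integer(),
      bsj_end = integer(), gene_id = character(), sample_id = character(),
      count = integer()
    ))
  }
  ex <- models$exons
  rows <- list()
  for (rid in unique(cand$read_id)) {
    b <- cand[cand$read_id == rid, ]
    b <- b[order(b$start), ]
    # inverted: some block earlier on the reference comes later on the read
    if (!any(diff(b$query_order) < 0)) next
    first <- b[1, ] # genomically first segment: acceptor side
    last <- b[nrow(b), ] # genomically last: donor side
    if (first$end - first$start < min_seg || last$end - last$start < min_seg) next
    exc <- ex[ex$chrom == first$chrom, ]
    acc_hit <- exc[abs(exc$start - first$start) <= tol, ]
    don_hit <- exc[abs(exc$end - last$end) <= tol, ]
    if (nrow(acc_hit) == 0 || nrow(don_hit) == 0) next
    gene <- intersect(acc_hit$gene_id, don_hit$gene_id)
    if (length(gene) == 0) next
    acc <- acc_hit$start[acc_hit$gene_id == gene[1]][1]
    don <- don_hit$end[don_hit$gene_id == gene[1]][1]
    if (acc >= don) next
    rows[[length(rows) + 1L]] <- tibble::tibble(
      chrom = first$chrom, bsj_start = acc, bsj_end = don,
      gene_id = gene[1], sample_id = first$sample_id
    )
  }
  if (length(rows) == 0) {
    return(tibble::tibble(
      bsj_id = character(), chrom = character(), bsj_start = integer(),
      bsj_end = integer(), gene_id = character(), sample_id = character(),
      count = integer()
    ))
  }
  counts <- dplyr::bind_rows(rows) |>
    dplyr::count(.data$chrom, .data$bsj_start, .data$bsj_end, .data$gene_id,
      .data$sample_id,
      name = "count"
    ) |>
    dplyr::mutate(bsj_id = sprintf("%s:%d|%d", .data$chrom, .data$bsj_start, .data$bsj_end))
  keep <- counts |>
    dplyr::group_by(.data$bsj_id) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop") |>
    dplyr::filter(.data$total >= min_support)
  counts |>
    dplyr::filter(.data$bsj_id %in% keep$bsj_id) |>
    dplyr::select(
      "bsj_id", "chrom", "bsj_start", "bsj_end", "gene_id",
      "sample_id", "count"
    )
}

#' Quantify and normalize circRNA expression against the linear transcript
#'
#' Two normalizations are computed and stored: the junction ratio
#' `circular / (circular + linear)` per sample (scale-invariant), and
#' library-size scaling of the circular counts by each sample's total linear
#' count (`count / total_linear * median(total_linear)`).
#'
#' @param bsj Output of [detect_bsj()].
#' @param linear_counts Tibble with `gene_id`, `sample_id`, `linear_count`
#'   (canonical-junction reads over the host locus).
#' @return Tibble: one row per `bsj_id` x `sample_id` with `count`,
#'   `linear_count`, `junction_ratio`, `norm_expr`. Rows with zero circular
#'   and linear counts carry `NA`.
#' @export
quantify_normalize <- function(bsj, linear_counts) {
  totals <- linear_counts |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(total_linear = sum(.data$linear_count), .groups = "drop")
  med <- stats::median(totals$total_linear)
  grid <- tidyr::expand_grid(
    bsj_id = unique(bsj$bsj_id),
    sample_id = unique(linear_counts$sample_id)
  ) |>
    dplyr::left_join(
      dplyr::distinct(bsj, .data$bsj_id, .data$chrom, .data$gene_id),
      by = "bsj_id"
    ) |>
    dplyr::left_join(
      dplyr::select(bsj, "bsj_id", "sample_id", "count"),
      by = c("bsj_id", "sample_id")
    ) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L)) |>
    dplyr::left_join(linear_counts, by = c("gene_id", "sample_id")) |>
    dplyr::mutate(linear_count = dplyr::coalesce(.data$linear_count, 0L)) |>
    dplyr::left_join(totals, by = "sample_id")
  grid |>
    dplyr::mutate(
      junction_ratio = dplyr::if_else(.data$count + .data$linear_count > 0,
        .data$count / (.data$count + .data$linear_count), NA_real_
      ),
      norm_expr = dplyr::if_else(.data$total_linear > 0,
        .data$count / .data$total_linear * med, NA_real_
      )
    ) |>
    dplyr::select(-"total_linear")
}

#' Call stage-regulated circRNAs
#'
#' Contrasts the combined low stages (default 0 and 1) against the combined
#' high stages (default 5 and 6) via [contrast_groups()]: regulated means
#' fold change beyond 1.5 in either direction with raw p below 0.05.
#'
#' @param norm Tibble from [quantify_normalize()] (uses `norm_expr`).
#' @param design A [stage_design()] tibble.
#' @param low_stages,high_stages Stages pooled into the two groups.
#' @param ... Passed to [contrast_groups()].
#' @return List with `contrasts` (per-feature table), `up`, `down`
#'   (regulated bsj ids) and `n_regulated`.
#' @export
call_regulated_circ <- function(norm, design, low_stages = c(0, 1),
                                high_stages = c(5, 6), ...) {
  lo <- design$sample_id[design$stage %in% low_stages]
  hi <- design$sample_id[design$stage %in% high_stages]
  if (length(lo) < 2 || length(hi) < 2) stop("each stage group needs >= 2 samples")
  mat <- norm |>
    dplyr::select("bsj_id", "sample_id", "norm_expr") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "norm_expr")
  m <- as.matrix(mat[, -1])
  rownames(m) <- mat$bsj_id
  m[is.na(m)] <- 0
  ct <- contrast_groups(m, lo, hi, ...)
  list(
    contrasts = ct,
    up = ct$feature_id[ct$regulated & ct$fold_change > 1],
    down = ct$feature_id[ct$regulated & ct$fold_change < 1],
    n_regulated = sum(ct$regulated)
  )
}

#' Rank circRNAs against a reference circRNA
#'
#' Dense 1-based ranking of mean normalized expression, descending; ties
#' share the smaller (better) rank. Reports the subset strictly above the
#' reference. When a host linear count matrix is given, linear ranks are
#' computed the same way.
#'
#' @param norm Tibble from [quantify_normalize()].
#' @param reference_id The reference `bsj_id` (must be present).
#' @param linear_counts Optional tibble (`gene_id`, `sample_id`,
#'   `linear_count`) for host mRNA ranks.
#' @return List with `ranks` (per-circRNA tibble `bsj_id`,
#'   `mean_norm_expr`, `circ_rank`, and `linear_rank` when available) and
#'   `above_reference` (bsj ids strictly above).
#' @export
rank_vs_reference <- function(norm, reference_id, linear_counts = NULL) {
  means <- norm |>
    dplyr::group_by(.data$bsj_id, .data$gene_id) |>
    dplyr::summarise(
      mean_norm_expr = mean(.data$norm_expr, na.rm = TRUE),
      .groups = "drop"
    )
  if (!reference_id %in% means$bsj_id) {
    stop("reference circRNA not found: ", reference_id)
  }
  means <- means |>
    dplyr::mutate(circ_rank = dplyr::dense_rank(dplyr::desc(.data$mean_norm_expr)))
  if (!is.null(linear_counts)) {
    lin <- linear_counts |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(mean_linear = mean(.data$linear_count), .groups = "drop") |>
      dplyr::mutate(linear_rank = dplyr::dense_rank(dplyr::desc(.data$mean_linear)))
    means <- dplyr::left_join(means,
      dplyr::select(lin, "gene_id", "linear_rank"),
      by = "gene_id"
    )
  }
  ref <- means$mean_norm_expr[means$bsj_id == reference_id]
  list(
    ranks = dplyr::arrange(means, .data$circ_rank),
    above_reference = means$bsj_id[means$mean_norm_expr > ref]
  )
}
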