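# Retained-intron detection: junction counting, PIR, stage correlation and
# long-read validation.

#' Count junction and intron-body reads per intron
#'
#' For every annotated intron and each read placement:
#' * exon-exon (`EE`): two blocks adjacent in both reference and query order
#'   abut the intron's boundaries exactly (donor block ends at the intron
#'   start, acceptor block starts at the intron end);
#' * exon-intron (`EI5` / `EI3`): a single contiguous block crosses the
#'   respective boundary with at least `min_overhang` bases on each side;
#' * `body`: a block lies fully inside the intron.
#'
#' A read increments at most one of `EE`, `EI5`, `EI3` per intron (priority
#' `EE` > `EI5` > `EI3`, relevant only for reads spanning a whole short
#' intron). `body_coverage_fraction` is the fraction of intron bases covered
#' by at least one read block.
#'
#' @param placements A `read_placements` tibble (one sample).
#' @param models A [gene_models] object on the same reference.
#' @param min_overhang Minimum bases on each side of an exon-intron boundary
#'   (default 8).
#' @param sample_id Sample label for the output (defaults to the one carried
#'   by `placements`).
#' @return Tibble with `intron_id`, `sample_id`, `EE`, `EI5`, `EI3`, `body`,
#'   `body_coverage_fraction`.
#' @export
count_junction_reads <- function(placements, models, min_overhang = 8L,
                                 sample_id = NULL) {
  stopifnot(inherits(models, "gene_models"))
  if (nrow(placements) > 0 &&
    !any(placements$chrom %in% models$introns$chrom) &&
    nrow(models$introns) > 0) {
    stop("placements and models share no reference sequence")
  }
  if (is.null(sample_id)) {
    sample_id <- if (nrow(placements) > 0) placements$sample_id[1] else NA_character_
  }
  intr <- models$introns
  out <- tibble::tibble(
    intron_id = intr$intron_id, sample_id = sample_id,
    EE = 0L, EI5 = 0L, EI3 = 0L, body = 0L, body_coverage_fraction = 0
  )
  if (nrow(placements) == 0 || nrow(intr) == 0) {
    return(out)
  }

  juncs <- splice_junctions(placements)
  ee <- juncs |>
    dplyr::inner_join(intr,
      by = dplyr::join_by("chrom", "junc_start" == "start", "junc_end" == "end")
    ) |>
    dplyr::distinct(.data$read_id, .data$intron_id) |>
    dplyr::count(.data$intron_id, name = "EE")

  bl <- placements
  ei_counts <- vector("list", nrow(intr))
  body_counts <- integer(nrow(intr))
  cov_frac <- numeric(nrow(intr))
  ee_reads <- juncs |>
    dplyr::inner_join(intr,
      by = dplyr::join_by("chrom", "junc_start" == "start", "junc_end" == "end")
    )
  for (i in seq_len(nrow(intr))) {
    it <- intr[i, ]
    b <- bl[bl$chrom == it$chrom & bl$start < it$end & bl$end > it$start, ]
    if (nrow(b) == 0) next
    already_ee <- unique(ee_reads$read_id[ee_reads$intron_id == it$intron_id])
    crosses5 <- b$start <= it$start - min_overhang & b$end >= it$start + min_overhang
    crosses3 <- b$start <= it$end - min_overhang & b$end >= it$end + min_overhang
    inside <- b$start >= it$start & b$end <= it$end
    reads5 <- setdiff(unique(b$read_id[crosses5]), already_ee)
    reads3 <- setdiff(unique(b$read_id[crosses3]), c(already_ee, reads5))
    ei_counts[[i]] <- c(length(reads5), length(reads3))
    body_counts[i] <- length(unique(b$read_id[inside]))
    ov_start <- pmax(b$start, it$start)
    ov_end <- pmin(b$end, it$end)
    keep <- ov_end > ov_start
    if (any(keep)) {
      cov <- IRanges::reduce(IRanges::IRanges(ov_start[keep] + 1L, ov_end[keep]))
      cov_frac[i] <- sum(IRanges::width(cov)) / (it$end - it$start)
    }
  }
  out$EI5 <- vapply(ei_counts, function(x) if (is.null(x)) 0L else as.integer(x[1]), integer(1))
  out$EI3 <- vapply(ei_counts, function(x) if (is.null(x)) 0L else as.integer(x[2]), integer(1))
  out$body <- body_counts
  out$body_coverage_fraction <- cov_frac
  m <- match(out$intron_id, ee$intron_id)
  out$EE <- ifelse(is.na(m), 0L, ee$EE[m])
  out
}

#' Percent intron retention (PIR)
#'
#' `EI = (EI5 + EI3) / 2`; `PIR = 100 * EI / (EE + EI)`. The numerator
#' averages the two boundary counts so that equal exon-intron and exon-exon
#' read flux gives PIR = 50. PIR is missing (`NA`) when `EE + EI = 0`.
#'
#' @param counts Output of [count_junction_reads()] (rows may span samples).
#' @return The input with `EI`, `PIR` and `detected`-ready columns appended.
#' @export
compute_pir <- function(counts) {
  if (any(counts$EE < 0 | counts$EI5 < 0 | counts$EI3 < 0 | counts$body < 0)) {
    stop("negative junction counts")
  }
  counts |>
    dplyr::mutate(
      EI = (.data$EI5 + .data$EI3) / 2,
      PIR = dplyr::if_else(.data$EE + .data$EI > 0,
        100 * .data$EI / (.data$EE + .data$EI), NA_real_
      )
    )
}

#' Detect retained introns per sample
#'
#' An intron is detected in a sample when `EI5 >= min_ei`, `EI3 >= min_ei`,
#' `body_coverage_fraction >= min_body` and `EE + EI >= min_total`.
#'
#' @param pir Output of [compute_pir()].
#' @param models A [gene_models] object (for the introns-per-expressed-gene
#'   summary; an expressed gene has at least `min_total` junction reads over
#'   its introns in that sample).
#' @param min_ei,min_body,min_total Detection thresholds (defaults 2, 0.5, 10).
#' @return The input with a logical `detected` column; attribute
#'   `introns_per_expressed_gene` holds the per-sample summary rate.
#' @export
detect_retained_introns <- function(pir, models = NULL, min_ei = 2L,
                                    min_body = 0.5, min_total = 10L) {
  out <- pir |>
    dplyr::mutate(
      detected = .data$EI5 >= min_ei & .data$EI3 >= min_ei &
        .data$body_coverage_fraction >= min_body &
        (.data$EE + .data$EI) >= min_total
    )
  if (!is.null(models)) {
    per_gene <- out |>
      dplyr::left_join(
        dplyr::select(models$introns, "intron_id", "gene_id"),
        by = "intron_id"
      ) |>
      dplyr::group_by(.data$sample_id, .data$gene_id) |>
      dplyr::summarise(
        expressed = sum(.data$EE + .data$EI) >= min_total,
        n_detected = sum(.data$detected), .groups = "drop"
      ) |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(
        rate = sum(.data$n_detected[.data$expressed]) / max(sum(.data$expressed), 1L),
        .groups = "drop"
      )
    attr(out, "introns_per_expressed_gene") <- per_gene
  }
  out
}

#' Validate detected introns with polyadenylated long reads
#'
#' An intron is validated when strictly more than `min_reads` polyA long
#' reads contain one contiguous reference block covering the entire intron
#' together with at least one base of each flanking exon (long reads report
#' the exon-intron structure of single molecules, so retention must appear
#' as an unbroken block).
#'
#' @param detected_ids Character vector of detected intron ids.
#' @param long_placements `read_placements` from long-read SAM (pooled over
#'   samples).
#' @param models A [gene_models] object.
#' @param min_reads Strict lower bound on supporting reads (default 10:
#'   an intron seen in exactly 10 reads is NOT validated).
#' @return Character vector: the validated subset of `detected_ids`. The
#'   per-intron support counts are attached as attribute `support`.
#' @export
validate_with_long_reads <- function(detected_ids, long_placements, models,
                                     min_reads = 10L) {
  intr <- models$introns[models$introns$intron_id %in% detected_ids, ]
  lp <- long_placements[long_placements$polyA, ]
  support <- integer(nrow(intr))
  names(support) <- intr$intron_id
  for (i in seq_len(nrow(intr))) {
    it <- intr[i, ]
    hit <- lp$chrom == it$chrom & lp$start <= it$start - 1L & lp$end >= it$end + 1L
    support[i] <- length(unique(lp$read_id[hit]))
  }
  out <- intr$intron_id[support > min_reads]
  attr(out, "support") <- support
  out
}

#' Spearman correlation of a per-sample feature with stage
#'
#' @param values Tibble with `feature_id`, `sample_id`, `value` (e.g. PIR or
#'   an editing index).
#' @param design A [stage_design()] tibble.
#' @param threshold Absolute rho at or above which a feature `passes`
#'   (default 0.8, two-sided).
#' @return Tibble with `feature_id`, `rho`, `n`, `passes`. Features with
#'   fewer than 3 non-missing samples or zero variance are skipped (logged
#'   in attribute `skipped`).
#' @export
correlate_with_stage <- function(values, design, threshold = 0.8) {
  df <- dplyr::inner_join(values, design, by = "sample_id")
  skipped <- character()
  rows <- df |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::group_map(function(d, key) {
      ok <- !is.na(d$value)
      if (sum(ok) < 3 || stats::sd(d$value[ok]) == 0 || stats::sd(d$stage[ok]) == 0) {
        return(tibble::tibble(
          feature_id = key$feature_id, rho = NA_real_,
          n = sum(ok), passes = FALSE, skipped = TRUE
        ))
      }
      rho <- stats::cor(d$value[ok], d$stage[ok], method = "spearman")
      tibble::tibble(
        feature_id = key$feature_id, rho = rho, n = sum(ok),
        passes = abs(rho) >= threshold, skipped = FALSE
      )
    }) |>
    dplyr::bind_rows()
  out <- dplyr::select(dplyr::filter(rows, !.data$skipped), -"skipped")
  attr(out, "skipped") <- rows$feature_id[rows$skipped]
  out
}
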