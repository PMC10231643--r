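# A-to-I editing: A>G mismatch pileup split by circular/linear read pool,
# per-sample editing indices, and stage trends. Inosine is read as
# guanosine, so editing appears as A>G on the gene strand (T>C on the
# reference for minus-strand genes).

#' Per-adenosine mismatch pileup split by read pool
#'
#' For every gene-strand adenosine covered by at least one read of a pool,
#' tallies total coverage, G calls (edited) and other non-A calls. Reads are
#' assigned to the `circular` pool when they carry the back-splice
#' supplementary-pair signature, otherwise to `linear`; an explicit
#' assignment can be supplied instead. Positions within `edge_buffer` bases
#' of a block end are excluded, as are reads without base calls.
#'
#' @param placements A `read_placements` tibble (one sample).
#' @param genome Named `DNAStringSet` or character vector.
#' @param models A [gene_models] object (supplies gene strand per contig).
#' @param pools Optional named character vector `read_id -> pool`.
#' @param edge_buffer Bases trimmed from each block end (default 3).
#' @param sample_id Sample label for the output.
#' @return Tibble with `chrom`, `pos` (0-based reference position of the
#'   gene-strand adenosine), `pool`, `sample_id`, `depth`, `g_count`,
#'   `other_count`.
#' @export
pileup_editing <- function(placements, genome, models, pools = NULL,
                           edge_buffer = 3L, sample_id = NULL) {
  genome_chr <- .genome_chars(genome)
  if (!all(unique(placements$chrom) %in% names(genome_chr))) {
    stop("placements reference sequences missing from genome")
  }
  if (is.null(sample_id)) {
    sample_id <- if (nrow(placements) > 0) placements$sample_id[1] else NA_character_
  }
  strand_of <- stats::setNames(
    models$transcripts$strand,
    models$transcripts$chrom
  )
  bl <- placements[!is.na(placements$bases), ]
  if (is.null(pools)) {
    pool_by_read <- bl |>
      dplyr::distinct(.data$read_id, .data$is_supplementary_pair) |>
      dplyr::mutate(pool = ifelse(.data$is_supplementary_pair, "circular", "linear"))
    pools <- stats::setNames(pool_by_read$pool, pool_by_read$read_id)
  }
  bl$pool <- unname(pools[bl$read_id])
  bl <- bl[!is.na(bl$pool), ]

  empty <- tibble::tibble(
    chrom = character(), pos = integer(), pool = character(),
    sample_id = character(), depth = integer(), g_count = integer(),
    other_count = integer()
  )
  w <- bl$end - bl$start
  bl <- bl[w > 2 * edge_buffer, ]
  if (nrow(bl) == 0) {
    return(empty)
  }
  lo <- bl$start + edge_buffer
  hi <- bl$end - edge_buffer
  refs <- substring(genome_chr[bl$chrom], lo + 1L, hi)
  reds <- substring(bl$bases, edge_buffer + 1L, (bl$end - bl$start) - edge_buffer)
  gene_strand <- strand_of[bl$chrom]
  ref_a <- ifelse(gene_strand == "+", "A", "T")
  edited <- ifelse(gene_strand == "+", "G", "C")
  rl <- strsplit(refs, "", fixed = TRUE)
  dl <- strsplit(reds, "", fixed = TRUE)
  blk <- rep(seq_len(nrow(bl)), lengths(rl))
  all_ref <- unlist(rl, use.names = FALSE)
  all_read <- unlist(dl, use.names = FALSE)
  posv <- lo[blk] + sequence(lengths(rl)) - 1L
  is_a <- all_ref == ref_a[blk]
  if (!any(is_a)) {
    return(empty)
  }
  tibble::tibble(
    chrom = bl$chrom[blk][is_a], pos = posv[is_a], pool = bl$pool[blk][is_a],
    g = all_read[is_a] == edited[blk][is_a],
    other = all_read[is_a] != edited[blk][is_a] & all_read[is_a] != all_ref[is_a]
  ) |>
    dplyr::group_by(.data$chrom, .data$pos, .data$pool) |>
    dplyr::summarise(
      depth = dplyr::n(), g_count = sum(.data$g),
      other_count = sum(.data$other), .groups = "drop"
    ) |>
    dplyr::mutate(sample_id = sample_id) |>
    dplyr::select(
      "chrom", "pos", "pool", "sample_id", "depth", "g_count",
      "other_count"
    )
}

#' Aggregate editing index per sample and pool
#'
#' The index is the aggregate `sum(G) / sum(depth)` over qualifying sites
#' (depth at least `min_depth` in that sample and pool) - G calls
#' normalized to the total sequence count at the individual sites. A
#' site-level table (`sites`) restricted to candidate editing sites -
#' `g_count >= min_g` with an edited fraction of at least `min_fraction`
#' in at least one sample, so that deep coverage of sequencing-error noise
#' does not call sites - is attached for reporting. Positions whose G
#' fraction exceeds 0.9 in the linear pool of every sample are masked in
#' both pools as homozygous-variant surrogates (the linear pool serves as
#' the control for DNA variation).
#'
#' @param table Pileup rows from [pileup_editing()], pooled over samples.
#' @param min_depth Minimum site depth (default 5).
#' @param min_g Minimum G calls for site-level reporting (default 2).
#' @param min_fraction Minimum edited fraction for site-level reporting
#'   (default 0.01).
#' @param mask_variants Apply the linear-pool variant mask (default TRUE).
#' @return Tibble with `sample_id`, `pool`, `index`, `n_sites`; attribute
#'   `sites` holds per-site fractions.
#' @export
editing_index <- function(table, min_depth = 5L, min_g = 2L,
                          min_fraction = 0.01, mask_variants = TRUE) {
  if (nrow(table) == 0) stop("empty editing site table")
  tab <- table
  if (mask_variants) {
    mask <- tab |>
      dplyr::filter(.data$pool == "linear", .data$depth > 0) |>
      dplyr::group_by(.data$chrom, .data$pos) |>
      dplyr::summarise(
        variant = all(.data$g_count / .data$depth > 0.9),
        .groups = "drop"
      ) |>
      dplyr::filter(.data$variant)
    tab <- dplyr::anti_join(tab, mask, by = c("chrom", "pos"))
  }
  qual <- tab[tab$depth >= min_depth, ]
  idx <- qual |>
    dplyr::group_by(.data$sample_id, .data$pool) |>
    dplyr::summarise(
      index = sum(.data$g_count) / sum(.data$depth),
      n_sites = dplyr::n(), .groups = "drop"
    )
  site_keep <- qual |>
    dplyr::group_by(.data$chrom, .data$pos, .data$pool) |>
    dplyr::filter(any(.data$g_count >= min_g &
      .data$g_count / .data$depth >= min_fraction)) |>
    dplyr::ungroup() |>
    dplyr::mutate(fraction = .data$g_count / .data$depth)
  attr(idx, "sites") <- site_keep
  idx
}

#' Stage trend of the editing index per pool
#'
#' Spearman rho and squared Pearson correlation of the per-sample index
#' against stage, separately for the circular and linear pools; the
#' difference of the two rhos is attached (`rho_contrast`) as the
#' DNA-variation control contrast.
#'
#' @param indices Output of [editing_index()] over all samples.
#' @param design A [stage_design()] tibble.
#' @return Tibble with `pool`, `rho`, `r_squared`, `n`. Pools with fewer
#'   than 3 samples or zero variance are flagged `NA`.
#' @export
editing_stage_trend <- function(indices, design) {
  df <- dplyr::inner_join(indices, design, by = "sample_id")
  out <- df |>
    dplyr::group_by(.data$pool) |>
    dplyr::summarise(
      n = dplyr::n(),
      rho = if (dplyr::n() >= 3 && stats::sd(.data$index) > 0) {
        stats::cor(.data$index, .data$stage, method = "spearman")
      } else {
        NA_real_
      },
      r_squared = if (dplyr::n() >= 3 && stats::sd(.data$index) > 0) {
        stats::cor(.data$index, .data$stage)^2
      } else {
        NA_real_
      },
      .groups = "drop"
    )
  if (all(c("circular", "linear") %in% out$pool)) {
    attr(out, "rho_contrast") <-
      out$rho[out$pool == "circular"] - out$rho[out$pool == "linear"]
  }
  out
}
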