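# Exon orthology by reciprocal best hits (RBH) of local alignments, and
# conserved regulated retained introns.

#' Local alignment of two DNA sequences
#'
#' Smith-Waterman local alignment (blastn-like scoring: match +2, mismatch
#' -3, gap open -5, gap extend -2 per base by default). Identity is
#' matches over aligned columns (gaps included); coverage is aligned query
#' bases over query length.
#'
#' @param seq_a,seq_b DNA strings (query, subject).
#' @param match,mismatch Substitution scores.
#' @param gap_open,gap_extend Gap penalties (negative).
#' @return List with `score`, `identity`, `coverage` (percent).
#' @export
align_local <- function(seq_a, seq_b, match = 2, mismatch = -3,
                        gap_open = -5, gap_extend = -2) {
  if (grepl("[^ACGTacgt]", seq_a) || grepl("[^ACGTacgt]", seq_b)) {
    stop("non-DNA characters in input sequence")
  }
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0) stop("empty sequence")
  sm <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = TRUE
  )
  al <- Biostrings::pairwiseAlignment(
    toupper(seq_a), toupper(seq_b),
    type = "local", substitutionMatrix = sm,
    gapOpening = -gap_open, gapExtension = -gap_extend
  )
  sc <- Biostrings::score(al)
  pat <- as.character(Biostrings::alignedPattern(al))
  ncols <- nchar(pat)
  if (sc <= 0 || ncols == 0) {
    return(list(score = max(sc, 0), identity = 0, coverage = 0))
  }
  matches <- Biostrings::nmatch(al)
  q_aligned <- nchar(gsub("-", "", pat, fixed = TRUE))
  list(
    score = sc,
    identity = 100 * matches / ncols,
    coverage = 100 * q_aligned / nchar(seq_a)
  )
}

#' Reciprocal best hits between two exon sets
#'
#' Every query is aligned to every subject; the best hit is taken by score,
#' with ties broken by higher identity and then lexicographic subject id. A
#' pair is an RBH when each exon is the other's best hit; it passes the
#' ortholog thresholds when identity and query coverage exceed the cutoffs
#' strictly in both directions.
#'
#' @param exons_a,exons_b Named character vectors of exon sequences.
#' @param min_identity,min_coverage Strict thresholds (defaults 70 and 50:
#'   identity exactly 70 fails).
#' @param ... Scoring parameters passed to [align_local()].
#' @return Tibble with `exon_a`, `exon_b`, `is_rbh`, `identity_ab`,
#'   `coverage_ab`, `identity_ba`, `coverage_ba`, `passes_thresholds`.
#' @export
reciprocal_best_hits <- function(exons_a, exons_b, min_identity = 70,
                                 min_coverage = 50, ...) {
  best_hit <- function(qs, ss) {
    # per query: list of (subject, score, identity, coverage)
    lapply(names(qs), function(qi) {
      hits <- lapply(names(ss), function(si) {
        h <- align_local(qs[[qi]], ss[[si]], ...)
        tibble::tibble(
          subject = si, score = h$score,
          identity = h$identity, coverage = h$coverage
        )
      })
      hits <- dplyr::bind_rows(hits)
      hits <- hits[order(-hits$score, -hits$identity, hits$subject), ]
      hits$query <- qi
      hits[1, ]
    }) |> dplyr::bind_rows()
  }
  ab <- best_hit(exons_a, exons_b)
  ba <- best_hit(exons_b, exons_a)
  rows <- lapply(seq_len(nrow(ab)), function(i) {
    qa <- ab$query[i]
    sb <- ab$subject[i]
    back <- ba[ba$query == sb, ]
    if (nrow(back) == 0 || back$subject != qa) {
      return(NULL)
    }
    tibble::tibble(
      exon_a = qa, exon_b = sb, is_rbh = TRUE,
      identity_ab = ab$identity[i], coverage_ab = ab$coverage[i],
      identity_ba = back$identity, coverage_ba = back$coverage,
      passes_thresholds = ab$identity[i] > min_identity &
        ab$coverage[i] > min_coverage &
        back$identity > min_identity & back$coverage > min_coverage
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      exon_a = character(), exon_b = character(), is_rbh = logical(),
      identity_ab = numeric(), coverage_ab = numeric(),
      identity_ba = numeric(), coverage_ba = numeric(),
      passes_thresholds = logical()
    )
  }
  out
}

#' Extract exon sequences from gene models
#'
#' Sequences are returned in transcript orientation (reverse complemented
#' for minus-strand genes) and named `transcript|sense_exon_index`.
#'
#' @param models A [gene_models] object.
#' @param genome Named `DNAStringSet` or character vector.
#' @return Named character vector.
#' @export
exon_sequences <- function(models, genome) {
  genome_chr <- .genome_chars(genome)
  ex <- models$exons
  out <- character(nrow(ex))
  nms <- character(nrow(ex))
  for (i in seq_len(nrow(ex))) {
    s <- substr(genome_chr[[ex$chrom[i]]], ex$start[i] + 1L, ex$end[i])
    n_ex <- sum(ex$transcript_id == ex$transcript_id[i])
    if (ex$strand[i] == "-") {
      s <- .revcomp(s)
      sense_idx <- n_ex - ex$exon_index[i] + 1L
    } else {
      sense_idx <- ex$exon_index[i]
    }
    out[i] <- s
    nms[i] <- sprintf("%s|%d", ex$transcript_id[i], sense_idx)
  }
  stats::setNames(out, nms)
}

#' Orthologous and conserved regulated introns
#'
#' An intron of species A (between sense exons k and k+1 of one transcript)
#' is orthologous to an intron of species B when both flanking exons form
#' passing RBH ortholog pairs and the pairs preserve adjacency (exon k maps
#' to exon j, exon k+1 to exon j+1 of one transcript of B). It is
#' conserved-regulated when additionally both introns are in their species'
#' regulated sets.
#'
#' @param pairs Output of [reciprocal_best_hits()] on exon sequences named
#'   `transcript|sense_exon_index`.
#' @param models_a,models_b [gene_models] objects of the two species.
#' @param regulated_a,regulated_b Character vectors of regulated intron ids
#'   (`transcript:I<genomic index>`).
#' @return Tibble with `intron_a`, `intron_b`, `conserved_regulated`.
#' @export
orthologous_introns <- function(pairs, models_a, models_b,
                                regulated_a = character(),
                                regulated_b = character()) {
  ok <- pairs[pairs$passes_thresholds, ]
  key <- function(x) strsplit(x, "|", fixed = TRUE)
  pa <- key(ok$exon_a)
  pb <- key(ok$exon_b)
  map <- tibble::tibble(
    tx_a = vapply(pa, `[`, character(1), 1),
    idx_a = as.integer(vapply(pa, `[`, character(1), 2)),
    tx_b = vapply(pb, `[`, character(1), 1),
    idx_b = as.integer(vapply(pb, `[`, character(1), 2))
  )
  sense_intron_id <- function(models, tx, sense_idx) {
    n_ex <- models$transcripts$n_exons[models$transcripts$transcript_id == tx]
    strand <- models$transcripts$strand[models$transcripts$transcript_id == tx]
    g_idx <- if (strand == "+") sense_idx else n_ex - sense_idx
    sprintf("%s:I%d", tx, g_idx)
  }
  rows <- list()
  for (i in seq_len(nrow(map))) {
    up <- map[i, ]
    dn <- map[map$tx_a == up$tx_a & map$idx_a == up$idx_a + 1L &
      map$tx_b == up$tx_b & map$idx_b == up$idx_b + 1L, ]
    if (nrow(dn) == 0) next
    ia <- sense_intron_id(models_a, up$tx_a, up$idx_a)
    ib <- sense_intron_id(models_b, up$tx_b, up$idx_b)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      intron_a = ia, intron_b = ib,
      conserved_regulated = ia %in% regulated_a & ib %in% regulated_b
    )
  }
  if (length(rows) == 0) {
    return(tibble::tibble(
      intron_a = character(), intron_b = character(),
      conserved_regulated = logical()
    ))
  }
  dplyr::bind_rows(rows)
}
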