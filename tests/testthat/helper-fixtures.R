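# Shared fixture builders: everything is generated in code at test time.

# write generator SAM records (possibly several samples) to one temp file and
# parse them back through the package reader
parse_records <- function(records, seqlens, sample_id = NA_character_) {
  path <- tempfile(fileext = ".sam")
  on.exit(unlink(path))
  write_sam(records, seqlens, path)
  read_spliced_alignments(path, sample_id = sample_id)
}

# SAM text from explicit lines (for hand-built edge cases)
parse_sam_lines <- function(lines, seqlens, sample_id = NA_character_) {
  path <- tempfile(fileext = ".sam")
  on.exit(unlink(path))
  hdr <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", names(seqlens), as.integer(seqlens))
  )
  writeLines(c(hdr, lines), path)
  read_spliced_alignments(path, sample_id = sample_id)
}

# a hand-built placements tibble (already-parsed form) for unit tests that
# do not need the SAM round trip
make_placements <- function(blocks, sample_id = "s1") {
  df <- tibble::as_tibble(blocks)
  if (!"strand" %in% names(df)) df$strand <- "+"
  if (!"chrom" %in% names(df)) df$chrom <- "c1"
  if (!"query_order" %in% names(df)) {
    df <- df |>
      dplyr::group_by(read_id) |>
      dplyr::arrange(start, .by_group = TRUE) |>
      dplyr::mutate(query_order = dplyr::row_number() - 1L) |>
      dplyr::ungroup()
  }
  if (!"bases" %in% names(df)) df$bases <- NA_character_
  if (!"is_supplementary_pair" %in% names(df)) df$is_supplementary_pair <- FALSE
  if (!"polyA" %in% names(df)) df$polyA <- FALSE
  df$sample_id <- sample_id
  df[, c(
    "read_id", "sample_id", "chrom", "strand", "start", "end",
    "query_order", "bases", "is_supplementary_pair", "polyA"
  )]
}

# two-exon gene model around one intron (200, 300) on contig c1
two_exon_models <- function(strand = "+") {
  gene_models(tibble::tibble(
    gene_id = "gA", transcript_id = "tA", chrom = "c1", strand = strand,
    start = c(100L, 300L), end = c(200L, 400L)
  ))
}

# random DNA string
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# independent affine-gap Smith-Waterman oracle (gap of length L costs
# open + ext * L), exhaustive DP - only for short sequences
sw_oracle <- function(a, b, match = 2, mismatch = -3, open = 5, ext = 2) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a)
  m <- length(b)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1) # best ending (i, j)
  E <- matrix(NEG, n + 1, m + 1) # gap in b (deletion from a)
  F <- matrix(NEG, n + 1, m + 1) # gap in a
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i - 1, j] - open - ext, E[i - 1, j] - ext)
      F[i, j] <- max(H[i, j - 1] - open - ext, F[i, j - 1] - ext)
      s <- if (a[i - 1] == b[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}
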