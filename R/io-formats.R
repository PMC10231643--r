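#' @title Readers and writers for the standard formats
#'
#' @description All plain-integer coordinates inside the package are 0-based
#' half-open `[start, end)` on the reference; conversion to and from the
#' 1-based conventions of GTF and SAM happens only in this file. Features are
#' reported in reference orientation; operations that depend on the transcribed
#' sequence (splice-site motifs, ORFs, regulatory-element scans) reverse
#' complement internally for minus-strand genes.
#'
#' @name io-formats
NULL

#' Construct a gene-model collection from an exon table
#'
#' @param exons A data frame with columns `gene_id`, `transcript_id`, `chrom`,
#'   `strand` (`"+"` or `"-"`), `start`, `end` (0-based half-open exon
#'   intervals).
#' @return An object of class `gene_models`: a list with tibbles `transcripts`,
#'   `exons` (with `exon_index` in genomic order) and `introns` (the gaps
#'   between consecutive exons, with `intron_id` of the form
#'   `"<transcript_id>:I<k>"`).
#' @details Exons of one transcript must be non-overlapping; they are sorted by
#'   start. Every derived intron must be at least 4 bp long (room for the
#'   dinucleotide motifs at both ends).
#' @export
gene_models <- function(exons) {
  exons <- tibble::as_tibble(exons)
  req <- c("gene_id", "transcript_id", "chrom", "strand", "start", "end")
  missing_cols <- setdiff(req, names(exons))
  if (length(missing_cols) > 0) {
    stop("exon table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!all(exons$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  if (any(exons$start >= exons$end)) stop("exon start must be < end")

  exons <- dplyr::arrange(exons, .data$transcript_id, .data$start) |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::mutate(exon_index = dplyr::row_number()) |>
    dplyr::ungroup()

  ovl <- exons |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(bad = any(.data$start[-1] < .data$end[-dplyr::n()]) &&
      dplyr::n() > 1, .groups = "drop")
  if (any(ovl$bad)) {
    stop(
      "overlapping exons in transcript(s): ",
      paste(ovl$transcript_id[ovl$bad], collapse = ", ")
    )
  }

  introns <- exons |>
    dplyr::group_by(
      .data$gene_id, .data$transcript_id, .data$chrom, .data$strand
    ) |>
    dplyr::reframe({
      es <- .data$start
      ee <- .data$end
      k <- length(es)
      tibble::tibble(
        intron_index = seq_len(max(k - 1L, 0L)),
        start = ee[-k],
        end = es[-1L]
      )
    }) |>
    dplyr::mutate(intron_id = paste0(.data$transcript_id, ":I", .data$intron_index)) |>
    dplyr::select(
      "intron_id", "gene_id", "transcript_id", "chrom", "strand",
      "intron_index", "start", "end"
    )
  if (nrow(introns) > 0 && any(introns$end - introns$start < 4)) {
    stop("derived intron shorter than 4 bp; exon structure invalid")
  }

  transcripts <- exons |>
    dplyr::group_by(
      .data$gene_id, .data$transcript_id, .data$chrom, .data$strand
    ) |>
    dplyr::summarise(
      tx_start = min(.data$start), tx_end = max(.data$end),
      n_exons = dplyr::n(), .groups = "drop"
    )

  structure(
    list(transcripts = transcripts, exons = exons, introns = introns),
    class = "gene_models"
  )
}

#' @export
print.gene_models <- function(x, ...) {
  cat(
    "<gene_models>", nrow(x$transcripts), "transcripts,",
    nrow(x$exons), "exons,", nrow(x$introns), "introns\n"
  )
  invisible(x)
}

#' Read gene models from a GTF file
#'
#' Only `exon` features are used; each must carry `gene_id` and
#' `transcript_id` attributes. GTF 1-based closed coordinates are converted to
#' the internal 0-based half-open convention.
#'
#' @param path Path to a GTF file.
#' @return A [gene_models] object.
#' @export
read_gene_models <- function(path) {
  lines <- readr::read_lines(path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9) stop("malformed GTF record at line ", i, ": fewer than 9 fields")
    if (f[3] == "exon" &&
      (!grepl("gene_id \"", f[9], fixed = TRUE) ||
        !grepl("transcript_id \"", f[9], fixed = TRUE))) {
      stop("malformed attribute string at line ", i, ": need gene_id and transcript_id")
    }
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) stop("no exon features in ", path)
  exons <- tibble::tibble(
    gene_id = gr$gene_id,
    transcript_id = gr$transcript_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  gene_models(exons)
}

#' Write gene models to a GTF file
#'
#' Emits one `exon` feature per exon, 1-based closed coordinates, sorted by
#' chromosome then start, so that a write/read round trip reproduces the
#' input exactly.
#'
#' @param models A [gene_models] object.
#' @param path Output path.
#' @export
write_gene_models <- function(models, path) {
  stopifnot(inherits(models, "gene_models"))
  ex <- dplyr::arrange(models$exons, .data$chrom, .data$start, .data$transcript_id)
  lines <- sprintf(
    "%s\tcircintron\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
    ex$chrom, ex$start + 1L, ex$end, ex$strand, ex$gene_id, ex$transcript_id
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read reference sequences from FASTA
#'
#' Sequences are uppercased and RNA `U` is converted to `T`.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_sequences <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(nm)) {
    stop("duplicate FASTA header: ", nm[duplicated(nm)][1])
  }
  if (any(Biostrings::width(raw) == 0)) {
    stop("empty sequence record: ", nm[Biostrings::width(raw) == 0][1])
  }
  seqs <- chartr("uU", "tT", as.character(raw))
  out <- Biostrings::DNAStringSet(toupper(seqs))
  names(out) <- nm
  out
}

#' Write sequences to FASTA
#' @param seqs A named `DNAStringSet` or named character vector.
#' @param path Output path.
#' @export
write_sequences <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read an interval set from a BED file
#'
#' @param path Path to a BED (>= 3 column) file.
#' @return A tibble with columns `chrom`, `start`, `end` (0-based half-open)
#'   and `label` (BED name field, or `"."`).
#' @export
read_intervals <- function(path) {
  gr <- rtracklayer::import(path)
  label <- if (!is.null(gr$name)) as.character(gr$name) else rep(".", length(gr))
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    label = label
  ) |> dplyr::arrange(.data$chrom, .data$start)
}

#' Write an interval set to BED6
#' @param intervals Tibble with `chrom`, `start`, `end`, optionally `label`,
#'   `score`, `strand`.
#' @param path Output path.
#' @export
write_intervals <- function(intervals, path) {
  iv <- tibble::as_tibble(intervals)
  if (!"label" %in% names(iv)) iv$label <- "."
  if (!"score" %in% names(iv)) iv$score <- 0
  if (!"strand" %in% names(iv)) iv$strand <- "."
  iv <- dplyr::arrange(iv, .data$chrom, .data$start)
  readr::write_lines(sprintf(
    "%s\t%d\t%d\t%s\t%g\t%s",
    iv$chrom, iv$start, iv$end, iv$label, iv$score, iv$strand
  ), path)
  invisible(path)
}

.cigar_allowed_ops <- c("M", "I", "D", "N", "S", "H")

#' Read spliced alignments from a SAM file
#'
#' Parses a headerful SAM file (with `@SQ` lines) into per-block read
#' placements. Each `N` CIGAR operation splits a new reference block.
#' Primary and supplementary records of one read (SA-tagged split reads,
#' e.g. back-splice-spanning reads) are merged into a single placement whose
#' `query_order` column records the 0-based rank of each reference-sorted
#' block along the read, derived from soft/hard-clip geometry. Aligned read
#' bases are carried per block (`bases`) for mismatch pileups; records with
#' insertions or deletions carry `NA` bases.
#'
#' @param path Path to a SAM file.
#' @param sample_id Optional sample label stored alongside every placement.
#' @return A tibble of class `read_placements`, one row per reference block,
#'   with columns `read_id`, `sample_id`, `chrom`, `strand`, `start`, `end`
#'   (0-based half-open), `query_order`, `bases`, `is_supplementary_pair`,
#'   `polyA`. Attributes `n_records`, `n_parsed`, `n_skipped` and `log`
#'   reconcile input records against parsed plus skipped reads.
#' @export
read_spliced_alignments <- function(path, sample_id = NA_character_) {
  bam <- Rsamtools::asBam(path,
    destination = tempfile(), overwrite = TRUE,
    indexDestination = FALSE
  )
  on.exit(unlink(bam), add = TRUE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "seq"),
    tag = c("SA", "XP")
  )
  gal <- GenomicAlignments::readGAlignments(bam, param = param)

  log <- character()
  n_records <- length(gal)
  if (n_records == 0) {
    out <- tibble::tibble(
      read_id = character(), sample_id = character(), chrom = character(),
      strand = character(), start = integer(), end = integer(),
      query_order = integer(), bases = character(),
      is_supplementary_pair = logical(), polyA = logical()
    )
    return(structure(out,
      class = c("read_placements", class(out)),
      n_records = 0L, n_parsed = 0L, n_skipped = 0L, log = log
    ))
  }

  cig <- GenomicAlignments::cigar(gal)
  ops <- unique(unlist(GenomicAlignments::explodeCigarOps(cig)))
  bad_ops <- setdiff(ops, .cigar_allowed_ops)
  if (length(bad_ops) > 0) {
    stop("unsupported CIGAR operation(s): ", paste(bad_ops, collapse = ", "))
  }

  flag <- S4Vectors::mcols(gal)$flag
  keep <- bitwAnd(flag, 4L) == 0L & bitwAnd(flag, 256L) == 0L
  n_skip_rec <- sum(!keep)
  if (n_skip_rec > 0) log <- c(log, sprintf("%d unmapped/secondary records skipped", n_skip_rec))
  gal <- gal[keep]
  flag <- flag[keep]
  cig <- cig[keep]

  qname <- S4Vectors::mcols(gal)$qname
  seqs <- as.character(S4Vectors::mcols(gal)$seq)
  xp <- S4Vectors::mcols(gal)$XP
  sa <- S4Vectors::mcols(gal)$SA
  is_supp <- bitwAnd(flag, 2048L) > 0L
  chrom <- as.character(GenomicAlignments::seqnames(gal))
  strnd <- as.character(GenomicAlignments::strand(gal))

  # reference blocks (split at N) and matching query-space ranges
  ref_blocks <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cig,
    pos = GenomicAlignments::start(gal), ops = c("M", "D"), reduce.ranges = TRUE
  )
  # leading soft/hard clip length (at most H then S at the CIGAR head)
  lead_clip <- integer(length(cig))
  h1 <- grepl("^\\d+[SH]", cig)
  lead_clip[h1] <- as.integer(sub("^(\\d+)[SH].*$", "\\1", cig[h1]))
  rest <- sub("^\\d+[SH]", "", cig)
  h2 <- h1 & grepl("^\\d+[SH]", rest)
  lead_clip[h2] <- lead_clip[h2] +
    as.integer(sub("^(\\d+)[SH].*$", "\\1", rest[h2]))
  has_indel <- grepl("[ID]", cig)

  nb <- S4Vectors::elementNROWS(ref_blocks)
  rb_all <- unlist(ref_blocks, use.names = FALSE)
  rec_idx <- rep(seq_along(cig), nb)
  w <- IRanges::width(rb_all)
  # query offset of each block within its record: N gaps consume no query
  first_of_rec <- c(TRUE, rec_idx[-1L] != rec_idx[-length(rec_idx)])
  run_cum <- cumsum(c(0L, w[-length(w)]))
  base_at_first <- run_cum[first_of_rec][cumsum(first_of_rec)]
  qstart <- lead_clip[rec_idx] + run_cum - base_at_first
  bases <- substring(seqs[rec_idx], qstart + 1L, qstart + w)
  bases[has_indel[rec_idx]] <- NA_character_
  if (is.null(xp)) xp <- rep(NA_integer_, length(cig))
  if (is.null(sa)) sa <- rep(NA_character_, length(cig))
  blocks <- tibble::tibble(
    rec = rec_idx, read_id = qname[rec_idx], chrom = chrom[rec_idx],
    strand = strnd[rec_idx],
    start = IRanges::start(rb_all) - 1L, end = IRanges::end(rb_all),
    query_start = qstart, bases = bases, supp = is_supp[rec_idx],
    polyA = !is.na(xp[rec_idx]) & xp[rec_idx] == 1L,
    has_sa = !is.na(sa[rec_idx])
  )

  # per-read merge and ordering, vectorized: sort blocks by (read, ref
  # position), then derive query ranks from a second sort on query offsets
  o1 <- order(blocks$read_id, blocks$start, blocks$end)
  b <- blocks[o1, ]
  grp <- cumsum(!duplicated(b$read_id))
  n_grp <- grp[length(grp)]
  grp_any <- function(x) (rowsum(as.integer(x), grp)[, 1] > 0)
  grp_n_distinct <- function(x) {
    rowsum(as.integer(!duplicated(paste(grp, x))), grp)[, 1]
  }
  supp_any <- grp_any(b$supp)
  pair_ok <- !supp_any |
    (grp_n_distinct(b$chrom) == 1 & grp_n_distinct(b$strand) == 1 &
      grp_n_distinct(b$rec) == 2 & !grp_any(!b$has_sa))
  polya_any <- grp_any(b$polyA)
  bad_reads <- unique(b$read_id[!pair_ok[grp]])
  if (length(bad_reads) > 0) {
    warning(length(bad_reads), " read(s) with inconsistent supplementary pairs skipped")
    log <- c(log, sprintf("read %s skipped: inconsistent SA pair", bad_reads))
  }
  skipped_reads <- length(bad_reads)
  o2 <- order(grp, b$query_start)
  qrank <- integer(nrow(b))
  qrank[o2] <- sequence(tabulate(grp, n_grp)) - 1L
  out <- tibble::tibble(
    read_id = b$read_id, sample_id = sample_id, chrom = b$chrom,
    strand = b$strand, start = b$start, end = b$end,
    query_order = qrank, bases = b$bases,
    is_supplementary_pair = supp_any[grp], polyA = polya_any[grp]
  )[pair_ok[grp], ]
  structure(tibble::as_tibble(out),
    class = c("read_placements", class(tibble::tibble())),
    n_records = n_records,
    n_parsed = length(unique(out$read_id)),
    n_skipped = n_skip_rec + skipped_reads,
    log = log
  )
}

#' Write SAM records
#'
#' Low-level writer used by the synthetic generator. Records are emitted with
#' a minimal `@HD`/`@SQ` header and sorted by chromosome, position and name
#' for deterministic output.
#'
#' @param records Tibble with columns `qname`, `flag`, `chrom`, `pos`
#'   (0-based), `mapq`, `cigar`, `seq`, and optionally `tags` (pre-formatted
#'   tab-separated SAM tags, `""` for none).
#' @param seqlens Named integer vector of reference lengths.
#' @param path Output path.
#' @export
write_sam <- function(records, seqlens, path) {
  rec <- tibble::as_tibble(records)
  if (is.null(rec$tags)) rec$tags <- ""
  rec <- dplyr::arrange(rec, .data$chrom, .data$pos, .data$qname, .data$flag)
  hdr <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", names(seqlens), as.integer(seqlens))
  )
  body <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*%s",
    rec$qname, rec$flag, rec$chrom, rec$pos + 1L, rec$mapq, rec$cigar,
    rec$seq, ifelse(nzchar(rec$tags), paste0("\t", rec$tags), "")
  )
  readr::write_lines(c(hdr, body), path)
  invisible(path)
}

#' Adjacent colinear splice junctions of each placement
#'
#' For every pair of blocks that are adjacent both in reference order and in
#' query order (i.e. joined by an `N` gap, not by a back-splice), returns the
#' junction interval `[donor_end, acceptor_start)` spanned by the gap.
#'
#' @param placements A `read_placements` tibble.
#' @return Tibble with `read_id`, `sample_id`, `chrom`, `junc_start`,
#'   `junc_end`.
#' @export
splice_junctions <- function(placements) {
  placements |>
    dplyr::group_by(.data$read_id, .data$sample_id, .data$chrom) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::reframe(
      junc_start = .data$end[-dplyr::n()],
      junc_end = .data$start[-1L],
      colinear = diff(.data$query_order) == 1L
    ) |>
    dplyr::filter(.data$colinear) |>
    dplyr::select(-"colinear")
}

# named character vector of contig sequences from DNAStringSet or character
.genome_chars <- function(genome) {
  if (is.character(genome)) {
    return(genome)
  }
  stats::setNames(as.character(genome), names(genome))
}
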