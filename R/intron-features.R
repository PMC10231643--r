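# Intron characterization: Alu content, splicing-regulatory-element (SRE)
# base coverage, position-weight-matrix splice-site strength, relative
# position along the pre-mRNA, and the retained-intron/circRNA gene
# association.

#' Alu content of introns
#'
#' `has_alu` is true when at least one Alu interval overlaps the intron by
#' one base or more (half-open intervals: an element abutting the intron
#' boundary does not count). When a control set is supplied, a 2x2 table of
#' Alu content in the two classes is tested with [chi2_2x2()] and the
#' percentages are reported rounded to integers.
#'
#' @param introns Tibble with `intron_id`, `chrom`, `start`, `end`.
#' @param alu Interval tibble (`chrom`, `start`, `end`) as from
#'   [read_intervals()].
#' @param control_introns Optional tibble of the same shape as `introns`.
#' @return Tibble `intron_id`, `has_alu`; with a control set, attributes
#'   `summary` (counts and integer percentages) and `chi2` are attached.
#' @export
alu_content <- function(introns, alu, control_introns = NULL) {
  overlap_flag <- function(iv) {
    flag <- logical(nrow(iv))
    for (ch in unique(iv$chrom)) {
      sel <- iv$chrom == ch
      a <- alu[alu$chrom == ch, ]
      if (nrow(a) == 0) next
      ir <- IRanges::IRanges(iv$start[sel] + 1L, iv$end[sel])
      ar <- IRanges::IRanges(a$start + 1L, a$end)
      flag[sel] <- IRanges::countOverlaps(ir, ar, minoverlap = 1L) > 0
    }
    flag
  }
  out <- tibble::tibble(intron_id = introns$intron_id, has_alu = overlap_flag(introns))
  if (!is.null(control_introns)) {
    ctrl <- overlap_flag(control_introns)
    a <- sum(out$has_alu)
    b <- sum(!out$has_alu)
    c_ <- sum(ctrl)
    d <- sum(!ctrl)
    attr(out, "summary") <- tibble::tibble(
      class = c("regulated", "control"),
      with_alu = c(a, c_), without_alu = c(b, d),
      pct_with_alu = c(round(100 * a / (a + b)), round(100 * c_ / (c_ + d)))
    )
    attr(out, "chi2") <- chi2_2x2(a, b, c_, d)
  }
  out
}

#' Fraction of bases covered by splicing regulatory elements
#'
#' Marks every base covered by at least one exact occurrence of a word from
#' the index (occurrences may overlap) and returns marked/total. Matching is
#' on the given strand's sequence only; pass gene-strand sequence.
#'
#' @param sequence A single DNA string (intron or intron-plus-flanks).
#' @param words Character vector of uppercase DNA words (6-8 bp enhancers,
#'   6 or 8 bp silencers).
#' @return Fraction in `[0, 1]`.
#' @export
sre_fraction <- function(sequence, words) {
  if (length(words) == 0) stop("empty SRE index")
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < min(nchar(words))) stop("sequence shorter than shortest word")
  covered <- logical(n)
  subj <- Biostrings::DNAString(sequence)
  for (w in unique(words)) {
    hits <- Biostrings::matchPattern(w, subj)
    if (length(hits) > 0) {
      for (k in seq_along(hits)) {
        covered[IRanges::start(hits)[k]:IRanges::end(hits)[k]] <- TRUE
      }
    }
  }
  sum(covered) / n
}

#' Read an SRE word list (one word per line)
#' @param path Plain-text file.
#' @return Uppercase character vector.
#' @export
read_sre_words <- function(path) {
  w <- toupper(trimws(readr::read_lines(path)))
  w[nzchar(w)]
}

# gene-strand window sequences for one intron:
# 5' site = 3 exonic + 6 intronic bases; 3' site = 20 intronic + 3 exonic.
.splice_windows <- function(intron, genome_chr) {
  cseq <- genome_chr[[intron$chrom]]
  if (intron$strand == "+") {
    w5 <- substr(cseq, intron$start - 3L + 1L, intron$start + 6L)
    w3 <- substr(cseq, intron$end - 20L + 1L, intron$end + 3L)
  } else {
    w5 <- .revcomp(substr(cseq, intron$end - 6L + 1L, intron$end + 3L))
    w3 <- .revcomp(substr(cseq, intron$start - 3L + 1L, intron$start + 20L))
  }
  list(w5 = w5, w3 = w3)
}

#' Estimate splice-site position weight matrices
#'
#' Builds 5' (9 nt: 3 exonic + 6 intronic) and 3' (23 nt: 20 intronic + 3
#' exonic) base-frequency matrices from the given introns, on the gene
#' strand, with a 0.5 pseudocount per base.
#'
#' @param introns Tibble of introns (`chrom`, `strand`, `start`, `end`).
#' @param genome Named `DNAStringSet` or character vector.
#' @return List with probability matrices `pwm5` (4 x 9) and `pwm3` (4 x 23).
#' @export
estimate_splice_pwm <- function(introns, genome) {
  genome_chr <- .genome_chars(genome)
  count <- function(seqs, len) {
    seqs <- seqs[nchar(seqs) == len & !grepl("[^ACGT]", seqs)]
    if (length(seqs) == 0) stop("no usable splice-site windows")
    m <- matrix(0.5, 4, len, dimnames = list(c("A", "C", "G", "T"), NULL))
    for (s in seqs) {
      ch <- strsplit(s, "")[[1]]
      for (j in seq_len(len)) m[ch[j], j] <- m[ch[j], j] + 1
    }
    sweep(m, 2, colSums(m), "/")
  }
  w <- lapply(seq_len(nrow(introns)), function(i) .splice_windows(introns[i, ], genome_chr))
  list(
    pwm5 = count(vapply(w, `[[`, character(1), "w5"), 9L),
    pwm3 = count(vapply(w, `[[`, character(1), "w3"), 23L)
  )
}

.pwm_score <- function(seq, pwm) {
  ri <- match(strsplit(seq, "")[[1]], rownames(pwm))
  if (length(ri) != ncol(pwm) || anyNA(ri)) {
    return(NA_real_)
  }
  sum(log2(pwm[cbind(ri, seq_len(ncol(pwm)))] / 0.25))
}

#' Score splice-site strength of introns
#'
#' Log2-odds score of each intron's 5' and 3' splice-site window against a
#' uniform background, under the supplied (or estimated) PWMs; the combined
#' score is the sum. Windows running off the contig are skipped (`NA`).
#'
#' @param introns Tibble of introns (`intron_id`, `chrom`, `strand`,
#'   `start`, `end`).
#' @param genome Named `DNAStringSet` or character vector.
#' @param pwm List with `pwm5`, `pwm3` as from [estimate_splice_pwm()].
#' @return Tibble with `intron_id`, `ss5_score`, `ss3_score`,
#'   `combined_score`.
#' @export
splice_site_scores <- function(introns, genome, pwm) {
  genome_chr <- .genome_chars(genome)
  rows <- lapply(seq_len(nrow(introns)), function(i) {
    it <- introns[i, ]
    len <- nchar(genome_chr[[it$chrom]])
    if (it$start < 20L || it$end + 20L > len) {
      return(tibble::tibble(
        intron_id = it$intron_id, ss5_score = NA_real_,
        ss3_score = NA_real_, combined_score = NA_real_
      ))
    }
    w <- .splice_windows(it, genome_chr)
    s5 <- .pwm_score(w$w5, pwm$pwm5)
    s3 <- .pwm_score(w$w3, pwm$pwm3)
    tibble::tibble(
      intron_id = it$intron_id, ss5_score = s5, ss3_score = s3,
      combined_score = s5 + s3
    )
  })
  dplyr::bind_rows(rows)
}

#' Relative position of introns along their transcript
#'
#' The pre-mRNA is normalized to length 100; the reported position is the
#' intron midpoint on that scale, orientation-corrected so 0 is the 5' end
#' of the transcript.
#'
#' @param introns Tibble of introns with `intron_id`, `transcript_id`,
#'   `start`, `end`.
#' @param models A [gene_models] object.
#' @return Tibble `intron_id`, `relative_position` (in `[0, 100]`),
#'   `length`.
#' @export
relative_positions <- function(introns, models) {
  tx <- models$transcripts
  introns |>
    dplyr::left_join(
      dplyr::select(tx, "transcript_id", "tx_start", "tx_end",
        tx_strand = "strand"
      ),
      by = "transcript_id"
    ) |>
    dplyr::mutate(
      mid = (.data$start + .data$end) / 2,
      relative_position = 100 * (.data$mid - .data$tx_start) /
        (.data$tx_end - .data$tx_start),
      relative_position = dplyr::if_else(.data$tx_strand == "-",
        100 - .data$relative_position, .data$relative_position
      ),
      length = .data$end - .data$start
    ) |>
    dplyr::select("intron_id", "relative_position", "length")
}

#' Mean and SD of intron lengths per class
#'
#' @param introns Tibble with `intron_id`, `start`, `end`.
#' @param classes Named list: class label -> character vector of intron ids.
#' @return Tibble `class`, `n`, `mean_length`, `sd_length`.
#' @export
intron_length_stats <- function(introns, classes) {
  purrr::imap(classes, function(ids, cl) {
    sel <- introns[introns$intron_id %in% ids, ]
    tibble::tibble(
      class = cl, n = nrow(sel),
      mean_length = mean(sel$end - sel$start),
      sd_length = stats::sd(sel$end - sel$start)
    )
  }) |> dplyr::bind_rows()
}

#' Association between regulated retained introns and circRNA expression
#'
#' 2x2 membership table over all genes: contains a regulated retained
#' intron (yes/no) x expresses a circRNA (yes/no), tested with
#' [chi2_2x2()].
#'
#' @param genes_with_ri,genes_with_circ,all_genes Character vectors of gene
#'   ids; the first two must be subsets of `all_genes`.
#' @return List with `table` (2x2 matrix), `chi2` (a `chi2_2x2`),
#'   `direction` (`"positive"` when RI genes are enriched for circRNAs).
#' @export
ri_circ_association <- function(genes_with_ri, genes_with_circ, all_genes) {
  stopifnot(
    all(genes_with_ri %in% all_genes),
    all(genes_with_circ %in% all_genes)
  )
  ri <- all_genes %in% genes_with_ri
  cc <- all_genes %in% genes_with_circ
  a <- sum(ri & cc)
  b <- sum(ri & !cc)
  c_ <- sum(!ri & cc)
  d <- sum(!ri & !cc)
  chi <- chi2_2x2(a, b, c_, d)
  expected_a <- sum(ri) * sum(cc) / length(all_genes)
  list(
    table = chi$table, chi2 = chi,
    direction = if (a >= expected_a) "positive" else "negative"
  )
}
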