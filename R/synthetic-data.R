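# Synthetic data generator: genomes, gene models, stage designs, spliced
# short reads, polyadenylated long reads, and edited back-splice reads, with
# truth tables for every downstream statistic.

# Fixed Alu-like 300 bp motif embedded in ~30% of introns. A synthetic
# constant, not a real repeat consensus.
.alu_motif <- paste0(
  "TTGTCGTGTCGAAGGTGATGGCCCTAACGGACACTTGCGAGCTGCACAGTCACAAAGCTTTCGGAAACAA",
  "GAGCATGAAAAAATGCAAAAATAATTGCTACAGTCGTCCCTTTACCACGCGCCGGAGATTCGGGAAGTGA",
  "GGCCCAGAATCAGAGAGGGAGATGGTACTGCACGTACTTGACAACCACCAAAATCCTCAACTAATTGTTG",
  "AACACATGTGTGACTTGCAGCGGTAAATTCATAGGTCCGAGATAAGATAAGGAGAGCCAGTATGGCATTG",
  "TTTAAGACGTGCAATTACTG"
)

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

#' Sample-to-stage design table
#'
#' Default mirrors the study layout: seven samples, one per Braak NFT stage
#' 0 through 6 (0 = aged-matched control).
#'
#' @param stages Integer vector of stages, one sample per entry.
#' @return Tibble with `sample_id`, `stage`.
#' @export
stage_design <- function(stages = 0:6) {
  stages <- as.integer(stages)
  if (any(stages < 0 | stages > 6)) stop("stages must be within 0-6")
  if (length(unique(stages)) < 2) stop("need >= 2 distinct stages")
  tibble::tibble(
    sample_id = sprintf("s%02d_b%d", seq_along(stages), stages),
    stage = stages
  )
}

#' Simulation profile
#'
#' Bundles the statistical knobs of the generator. Defaults encode the study
#' conditions: a circular/linear abundance ratio of 1%, and a circular-pool
#' A-to-I editing rate rising threefold (0.02 to 0.06) from stage 0 to 6
#' while the linear pool stays flat at 0.02.
#'
#' @param n_genes Number of genes.
#' @param read_depth Junction reads per intron per sample (short reads) and
#'   linear reads per gene per sample (circRNA libraries).
#' @param long_read_depth Long (nanopore-like) reads per gene per sample.
#'   A scalar, or a vector of length `n_genes` to place individual genes on
#'   either side of validation thresholds.
#' @param circ_fraction Circular/linear abundance ratio (default 0.01).
#' @param rnase_r_enrichment Fold enrichment of circular molecules in the
#'   circRNA library (RNase R digestion of linear RNA before sequencing;
#'   default 40, a mid-range enrichment for this protocol). Multiplies the
#'   expected circular read count in the emitted library without changing
#'   the underlying abundance ratio.
#' @param error_rate Per-base uniform substitution error.
#' @param linear_editing_rate Constant A>G rate in the linear pool.
#' @param editing_trend Function `stage -> true editing rate` for the
#'   circular pool.
#' @param pir_trend Function `(gene_index, stage) -> true PIR` (fraction in
#'   `[0, 1]`) of the gene's designated retained intron. The default makes
#'   odd-numbered genes trend linearly 0 to 0.6 across stages 0-6 and
#'   even-numbered genes flat at 0.3.
#' @param circ_stage_multiplier Function `(gene_index, stage) -> multiplier`
#'   on the expected circular count. Default: odd genes rise `1 + stage/2`,
#'   even genes constant 1.
#' @param seed Integer master seed; each output file derives its own stream.
#' @return List of class `simulation_profile`.
#' @export
simulation_profile <- function(n_genes = 8,
                               read_depth = 150,
                               long_read_depth = 30,
                               circ_fraction = 0.01,
                               rnase_r_enrichment = 40,
                               error_rate = 0.001,
                               linear_editing_rate = 0.02,
                               editing_trend = function(stage) 0.02 * (1 + 2 * stage / 6),
                               pir_trend = function(gene_index, stage) {
                                 if (gene_index %% 2 == 1) 0.6 * stage / 6 else 0.3
                               },
                               circ_stage_multiplier = function(gene_index, stage) {
                                 if (gene_index %% 2 == 1) 1 + stage / 2 else 1
                               },
                               seed = 1L) {
  stopifnot(
    n_genes >= 1, read_depth > 0, all(long_read_depth >= 0),
    circ_fraction >= 0, circ_fraction <= 1, rnase_r_enrichment >= 1,
    error_rate >= 0, error_rate <= 1,
    linear_editing_rate >= 0, linear_editing_rate <= 1
  )
  structure(
    list(
      n_genes = as.integer(n_genes), read_depth = as.integer(read_depth),
      long_read_depth = long_read_depth, circ_fraction = circ_fraction,
      rnase_r_enrichment = rnase_r_enrichment,
      error_rate = error_rate, linear_editing_rate = linear_editing_rate,
      editing_trend = editing_trend, pir_trend = pir_trend,
      circ_stage_multiplier = circ_stage_multiplier, seed = as.integer(seed)
    ),
    class = "simulation_profile"
  )
}

#' Generate synthetic gene models and a genome
#'
#' Each gene lives on its own contig: 3-8 exons of 80-300 bp separated by
#' introns of 100-2,000 bp beginning `GT` and ending `AG` on the gene strand.
#' One intron per gene is designated "retained" (drawn 300-1,500 bp so that
#' 150 bp reads fit inside its body); about 30% of sufficiently long introns
#' carry an embedded 300 bp Alu-like motif; exons 2 and 3 are at least
#' 150 bp so that a back-splice circle across them supports read segments
#' and editing-site windows. Roughly every third gene is on the minus
#' strand.
#'
#' @param n_genes Number of genes (>= 1).
#' @param seed Integer seed; output is reproducible byte-for-byte.
#' @return List with `genome` (DNAStringSet), `models` ([gene_models]),
#'   `alu` (interval tibble), `retained` (designated retained introns),
#'   `circles` (per-gene back-splice circle: the reference spans of sense
#'   exons 2 and 3), and `edit_sites` (gene-strand adenosine positions used
#'   for editing simulation).
#' @export
generate_gene_models <- function(n_genes, seed = 1L) {
  stopifnot(n_genes >= 1)
  set.seed(seed)
  pad <- 100L
  genome <- character(n_genes)
  chroms <- sprintf("c%03d", seq_len(n_genes))
  exon_rows <- list()
  alu_rows <- list()
  ret_rows <- list()
  circ_rows <- list()
  site_rows <- list()

  for (g in seq_len(n_genes)) {
    gene_id <- sprintf("g%03d", g)
    tx_id <- sprintf("t%03d", g)
    strand <- if (g %% 3 == 0) "-" else "+"
    n_ex <- sample(3:8, 1)
    ex_len <- sample(80:300, n_ex, replace = TRUE)
    ex_len[2:3] <- sample(150:300, 2, replace = TRUE)
    in_len <- sample(100:2000, n_ex - 1, replace = TRUE)
    ret_idx <- sample(seq_len(n_ex - 1), 1)
    in_len[ret_idx] <- sample(300:1500, 1)

    # build the sense-orientation locus and record sense coordinates
    segs <- character(2 * n_ex - 1)
    sense_start <- integer(n_ex)
    sense_in_start <- integer(n_ex - 1)
    pos <- pad
    for (k in seq_len(n_ex)) {
      segs[2 * k - 1] <- .rand_dna(ex_len[k])
      sense_start[k] <- pos
      pos <- pos + ex_len[k]
      if (k < n_ex) {
        body <- .rand_dna(in_len[k] - 4L)
        iseq <- paste0("GT", body, "AG")
        if (in_len[k] >= 320 && stats::runif(1) < 0.3) {
          off <- 10L # motif sits 10 bp inside the intron
          substr(iseq, off + 1L, off + 300L) <- .alu_motif
          alu_rows[[length(alu_rows) + 1L]] <- tibble::tibble(
            gene_id = gene_id, sense_start = pos + off,
            sense_end = pos + off + 300L
          )
        }
        segs[2 * k] <- iseq
        sense_in_start[k] <- pos
        pos <- pos + in_len[k]
      }
    }
    sense_len <- pos + pad
    sense_seq <- paste0(.rand_dna(pad), paste(segs, collapse = ""), .rand_dna(pad))
    stopifnot(nchar(sense_seq) == sense_len)
    to_ref <- function(a, b) {
      if (strand == "+") c(a, b) else c(sense_len - b, sense_len - a)
    }
    genome[g] <- if (strand == "+") sense_seq else .revcomp(sense_seq)

    for (k in seq_len(n_ex)) {
      ab <- to_ref(sense_start[k], sense_start[k] + ex_len[k])
      exon_rows[[length(exon_rows) + 1L]] <- tibble::tibble(
        gene_id = gene_id, transcript_id = tx_id, chrom = chroms[g],
        strand = strand, start = ab[1], end = ab[2], sense_index = k
      )
    }
    # designated retained intron (reference coordinates)
    ri <- to_ref(sense_in_start[ret_idx], sense_in_start[ret_idx] + in_len[ret_idx])
    # genomic intron index: on '-' strand sense intron k is genomic intron n_ex - k
    g_idx <- if (strand == "+") ret_idx else n_ex - ret_idx
    ret_rows[[length(ret_rows) + 1L]] <- tibble::tibble(
      gene_id = gene_id, transcript_id = tx_id, chrom = chroms[g],
      strand = strand, intron_id = sprintf("%s:I%d", tx_id, g_idx),
      start = ri[1], end = ri[2], sense_intron_index = ret_idx
    )
    # circle: sense exons 2 and 3
    c2 <- to_ref(sense_start[2], sense_start[2] + ex_len[2])
    c3 <- to_ref(sense_start[3], sense_start[3] + ex_len[3])
    rA <- if (c2[1] < c3[1]) c2 else c3 # reference-earlier exon of the circle
    rB <- if (c2[1] < c3[1]) c3 else c2
    circ_rows[[length(circ_rows) + 1L]] <- tibble::tibble(
      gene_id = gene_id, transcript_id = tx_id, chrom = chroms[g],
      strand = strand, a_start = rA[1], a_end = rA[2],
      b_start = rB[1], b_end = rB[2],
      circ_len = (rA[2] - rA[1]) + (rB[2] - rB[1])
    )
    # editing sites: gene-strand adenosines 10-79 bp into sense exon 2
    ex2 <- substr(sense_seq, sense_start[2] + 1L, sense_start[2] + ex_len[2])
    a_off <- which(strsplit(ex2, "")[[1]] == "A") - 1L
    a_off <- a_off[a_off >= 10 & a_off < 80]
    a_off <- utils::head(a_off, 3)
    for (o in a_off) {
      ab <- to_ref(sense_start[2] + o, sense_start[2] + o + 1L)
      site_rows[[length(site_rows) + 1L]] <- tibble::tibble(
        gene_id = gene_id, chrom = chroms[g], strand = strand,
        pos = ab[1], sense_offset = o
      )
    }
  }
  names(genome) <- chroms
  exons <- dplyr::bind_rows(exon_rows)
  models <- gene_models(dplyr::select(exons, -"sense_index"))

  alu <- if (length(alu_rows) > 0) {
    dplyr::bind_rows(alu_rows) |>
      dplyr::left_join(
        dplyr::distinct(exons, .data$gene_id, .data$chrom, .data$strand),
        by = "gene_id"
      ) |>
      dplyr::rowwise() |>
      dplyr::mutate(
        len = nchar(genome[[.data$chrom]]),
        start = ifelse(.data$strand == "+", .data$sense_start, .data$len - .data$sense_end),
        end = ifelse(.data$strand == "+", .data$sense_end, .data$len - .data$sense_start),
        label = "AluY_synth"
      ) |>
      dplyr::ungroup() |>
      dplyr::select("chrom", "start", "end", "label", "gene_id")
  } else {
    tibble::tibble(
      chrom = character(), start = integer(), end = integer(),
      label = character(), gene_id = character()
    )
  }

  list(
    genome = Biostrings::DNAStringSet(genome),
    models = models,
    alu = alu,
    retained = dplyr::bind_rows(ret_rows),
    circles = dplyr::bind_rows(circ_rows),
    edit_sites = dplyr::bind_rows(site_rows)
  )
}

# apply uniform substitution errors to a character vector of read sequences
.apply_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) {
    return(seqs)
  }
  chars <- strsplit(seqs, "", fixed = TRUE)
  lens <- lengths(chars)
  hits <- stats::rbinom(length(seqs), lens, rate)
  idx <- which(hits > 0)
  for (i in idx) {
    p <- sample.int(lens[i], hits[i])
    alt <- vapply(chars[[i]][p], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
    chars[[i]][p] <- alt
    seqs[i] <- paste(chars[[i]], collapse = "")
  }
  seqs
}

.block_seq <- function(chrom_seq, start, end) substr(chrom_seq, start + 1L, end)

#' Simulate spliced short reads
#'
#' For every intron and sample, `read_depth` 150 bp junction reads are drawn.
#' For the gene's designated retained intron with true PIR `p`, a read is an
#' exon-intron read with probability `q = 2p/(1 + p)` (so that the averaged
#' PIR numerator recovers `p` in expectation) and an exon-exon read
#' otherwise; exon-intron reads split evenly between the 5' and 3'
#' boundaries, and `Binomial(read_depth/2, p)` intron-body reads are added.
#' All other introns receive exon-exon reads only.
#'
#' @param sim Result of [generate_gene_models()].
#' @param design A [stage_design()] tibble.
#' @param profile A [simulation_profile()].
#' @param emit_reads Emit read records (default). With `FALSE` only the
#'   truth-table counts are drawn - a fast mode for count-level experiments
#'   (its random stream differs from the full mode).
#' @return List with `records` (SAM record tibble with `sample_id`) and
#'   `truth` (per intron x sample: true PIR and emitted counts).
#' @export
simulate_short_reads <- function(sim, design, profile, emit_reads = TRUE) {
  set.seed(profile$seed + 1L)
  if (any(profile$read_depth <= 0)) stop("read depth must be positive for every sample")
  models <- sim$models
  rec <- list()
  truth <- list()
  genome_chr <- as.character(sim$genome)

  for (s in seq_len(nrow(design))) {
    sid <- design$sample_id[s]
    stg <- design$stage[s]
    for (g in seq_len(nrow(models$transcripts))) {
      tx <- models$transcripts[g, ]
      ex <- models$exons[models$exons$transcript_id == tx$transcript_id, ]
      intr <- models$introns[models$introns$transcript_id == tx$transcript_id, ]
      ret <- sim$retained[sim$retained$transcript_id == tx$transcript_id, ]
      cseq <- genome_chr[[tx$chrom]]
      n <- profile$read_depth
      for (j in seq_len(nrow(intr))) {
        it <- intr[j, ]
        is_ret <- it$intron_id == ret$intron_id
        p <- if (is_ret) profile$pir_trend(g, stg) else 0
        stopifnot(p >= 0, p <= 1)
        q <- if (p > 0) 2 * p / (1 + p) else 0
        n_ei <- stats::rbinom(1, n, q)
        n_ee <- n - n_ei
        n_ei5 <- stats::rbinom(1, n_ei, 0.5)
        n_ei3 <- n_ei - n_ei5
        n_body <- stats::rbinom(1, round(n / 2), p)
        ex5 <- ex[ex$end == it$start, ]
        ex3 <- ex[ex$start == it$end, ]
        ilen <- it$end - it$start
        qn <- function(kind, i) {
          sprintf("sr:%s:%s:%s:%s:%d", tx$gene_id, it$intron_id, sid, kind, i)
        }

        if (emit_reads && n_ee > 0) {
          o1 <- min(75L, ex5$end - ex5$start)
          o2 <- min(75L, ex3$end - ex3$start)
          seq <- paste0(
            .block_seq(cseq, it$start - o1, it$start),
            .block_seq(cseq, it$end, it$end + o2)
          )
          rec[[length(rec) + 1L]] <- tibble::tibble(
            qname = qn("ee", seq_len(n_ee)), flag = 0L, chrom = tx$chrom,
            pos = it$start - o1, mapq = 60L,
            cigar = sprintf("%dM%dN%dM", o1, ilen, o2),
            seq = .apply_errors(rep(seq, n_ee), profile$error_rate),
            sample_id = sid, tags = ""
          )
        }
        if (emit_reads && n_ei5 > 0) {
          amin <- max(8L, 150L - (ex5$end - ex5$start))
          amax <- min(142L, ilen - 8L)
          a <- sample(seq(amin, amax), n_ei5, replace = TRUE)
          starts <- it$start - (150L - a)
          rec[[length(rec) + 1L]] <- tibble::tibble(
            qname = qn("ei5", seq_len(n_ei5)), flag = 0L, chrom = tx$chrom,
            pos = starts, mapq = 60L, cigar = "150M",
            seq = .apply_errors(
              substring(cseq, starts + 1L, starts + 150L),
              profile$error_rate
            ),
            sample_id = sid, tags = ""
          )
        }
        if (emit_reads && n_ei3 > 0) {
          bmin <- max(8L, 150L - (ex3$end - ex3$start))
          bmax <- min(142L, ilen - 8L)
          b <- sample(seq(bmin, bmax), n_ei3, replace = TRUE)
          starts <- it$end - b
          rec[[length(rec) + 1L]] <- tibble::tibble(
            qname = qn("ei3", seq_len(n_ei3)), flag = 0L, chrom = tx$chrom,
            pos = starts, mapq = 60L, cigar = "150M",
            seq = .apply_errors(
              substring(cseq, starts + 1L, starts + 150L),
              profile$error_rate
            ),
            sample_id = sid, tags = ""
          )
        }
        if (emit_reads && n_body > 0) {
          starts <- sample(seq(it$start, it$end - 150L), n_body, replace = TRUE)
          rec[[length(rec) + 1L]] <- tibble::tibble(
            qname = qn("bd", seq_len(n_body)), flag = 0L, chrom = tx$chrom,
            pos = starts, mapq = 60L, cigar = "150M",
            seq = .apply_errors(
              substring(cseq, starts + 1L, starts + 150L),
              profile$error_rate
            ),
            sample_id = sid, tags = ""
          )
        }
        truth[[length(truth) + 1L]] <- tibble::tibble(
          gene_id = tx$gene_id, transcript_id = tx$transcript_id,
          intron_id = it$intron_id, sample_id = sid, stage = stg,
          true_pir = p, n_ee = n_ee, n_ei5 = n_ei5, n_ei3 = n_ei3,
          n_body = n_body
        )
      }
    }
  }
  list(records = dplyr::bind_rows(rec), truth = dplyr::bind_rows(truth))
}

#' Simulate polyadenylated long reads
#'
#' Full-length transcript reads (one alignment, exons joined by `N` gaps)
#' carrying a polyA tag (`XP:i:1`). A fraction equal to the gene's true PIR
#' retains the designated intron as one contiguous reference block.
#'
#' @inheritParams simulate_short_reads
#' @return List with `records` and `truth` (per gene x sample: reads emitted
#'   and reads retaining the intron).
#' @export
simulate_long_reads <- function(sim, design, profile) {
  set.seed(profile$seed + 2L)
  models <- sim$models
  genome_chr <- as.character(sim$genome)
  depth <- profile$long_read_depth
  if (length(depth) == 1) depth <- rep(depth, nrow(models$transcripts))
  rec <- list()
  truth <- list()
  for (s in seq_len(nrow(design))) {
    sid <- design$sample_id[s]
    stg <- design$stage[s]
    for (g in seq_len(nrow(models$transcripts))) {
      tx <- models$transcripts[g, ]
      ex <- models$exons[models$exons$transcript_id == tx$transcript_id, ]
      ret <- sim$retained[sim$retained$transcript_id == tx$transcript_id, ]
      cseq <- genome_chr[[tx$chrom]]
      p <- profile$pir_trend(g, stg)
      n <- depth[g]
      if (n == 0) next
      n_ret <- stats::rbinom(1, n, p)
      mk <- function(retain, count, kind) {
        if (count == 0) {
          return(NULL)
        }
        b <- ex[order(ex$start), c("start", "end")]
        if (retain) {
          # merge the two exons flanking the retained intron with its body
          hit <- which(b$end == ret$start)
          b$end[hit] <- b$end[hit + 1L]
          b <- b[-(hit + 1L), ]
        }
        gaps <- b$start[-1L] - b$end[-nrow(b)]
        cigar <- paste0(
          paste0(
            b$end - b$start, "M",
            c(ifelse(gaps > 0, paste0(gaps, "N"), ""), "")
          ),
          collapse = ""
        )
        seq <- paste(mapply(function(a, bb) .block_seq(cseq, a, bb), b$start, b$end),
          collapse = ""
        )
        tibble::tibble(
          qname = sprintf("lr:%s:%s:%s:%d", tx$gene_id, sid, kind, seq_len(count)),
          flag = 0L, chrom = tx$chrom, pos = b$start[1], mapq = 60L,
          cigar = cigar,
          seq = .apply_errors(rep(seq, count), profile$error_rate),
          sample_id = sid, tags = "XP:i:1"
        )
      }
      rec[[length(rec) + 1L]] <- mk(TRUE, n_ret, "ret")
      rec[[length(rec) + 1L]] <- mk(FALSE, n - n_ret, "spl")
      truth[[length(truth) + 1L]] <- tibble::tibble(
        gene_id = tx$gene_id, intron_id = ret$intron_id, sample_id = sid,
        stage = stg, true_pir = p, n_reads = n, n_retained = n_ret
      )
    }
  }
  list(records = dplyr::bind_rows(rec), truth = dplyr::bind_rows(truth))
}

#' Simulate circRNA libraries: back-splice and matched linear reads
#'
#' Back-splice-spanning reads are emitted as primary/supplementary record
#' pairs whose reference order is inverted relative to query order (the
#' split-read signature of a circular junction). The expected per-sample
#' circular count is `circ_fraction x read_depth x stage multiplier`
#' (Poisson). Each gene also receives `read_depth` canonical junction reads
#' and `read_depth` exon-body reads over the same locus (the linear pool).
#' Designated gene-strand adenosines inside the circle are converted to G at
#' `editing_trend(stage)` in circular reads and at the constant
#' `linear_editing_rate` in linear reads.
#'
#' @inheritParams simulate_short_reads
#' @return List with `records`, `truth` (per gene x sample counts) and
#'   `site_truth` (per editing site x sample true rates).
#' @export
simulate_circ_reads <- function(sim, design, profile) {
  set.seed(profile$seed + 3L)
  genome_chr <- as.character(sim$genome)
  rec <- list()
  truth <- list()
  site_truth <- list()

  # convert gene-strand adenosines (reference A, or T on '-' genes) to their
  # edited base at the given rate, independently per read and site;
  # `starts` gives each read segment's reference start
  edit_strings <- function(seqs, starts, sites, rate) {
    if (length(sites) == 0 || rate <= 0 || length(seqs) == 0) {
      return(seqs)
    }
    if (length(starts) == 1) starts <- rep(starts, length(seqs))
    n <- nchar(seqs)
    for (s in sites) {
      off <- s - starts + 1L
      hit <- off >= 1L & off <= n & stats::runif(length(seqs)) < rate
      if (!any(hit)) next
      base <- substr(seqs[hit], off[hit], off[hit])
      repl <- ifelse(base == "A", "G", ifelse(base == "T", "C", base))
      tmp <- seqs[hit]
      substr(tmp, off[hit], off[hit]) <- repl
      seqs[hit] <- tmp
    }
    seqs
  }

  for (s in seq_len(nrow(design))) {
    sid <- design$sample_id[s]
    stg <- design$stage[s]
    circ_rate <- profile$editing_trend(stg)
    for (g in seq_len(nrow(sim$circles))) {
      ci <- sim$circles[g, ]
      cseq <- genome_chr[[ci$chrom]]
      sites <- sim$edit_sites$pos[sim$edit_sites$gene_id == ci$gene_id]
      mult <- profile$circ_stage_multiplier(g, stg)
      n_lin <- profile$read_depth
      n_circ <- stats::rpois(
        1, profile$circ_fraction * n_lin * mult * profile$rnase_r_enrichment
      )

      # back-splice reads: [tail of downstream exon][head of upstream exon];
      # edited sites always sit within the first 90 bases of the acceptor
      # exon, which every read's second segment (>= 90 bases) covers
      if (n_circ > 0) {
        a <- sample(20:60, n_circ, replace = TRUE)
        b <- 150L - a
        part1 <- substring(cseq, ci$b_end - a + 1L, ci$b_end)
        part2 <- substring(cseq, ci$a_start + 1L, ci$a_start + b)
        part1 <- edit_strings(part1, ci$b_end - a, sites, circ_rate)
        part2 <- edit_strings(part2, ci$a_start, sites, circ_rate)
        full <- .apply_errors(paste0(part1, part2), profile$error_rate)
        pos1 <- ci$b_end - a
        pos2 <- ci$a_start
        rec[[length(rec) + 1L]] <- tibble::tibble(
          qname = rep(sprintf("bsj:%s:%s:%d", ci$gene_id, sid, seq_len(n_circ)),
            each = 2
          ),
          flag = rep(c(0L, 2048L), n_circ),
          chrom = ci$chrom,
          pos = as.vector(rbind(pos1, rep(pos2, n_circ))),
          mapq = 60L,
          cigar = as.vector(rbind(
            sprintf("%dM%dS", a, b), sprintf("%dS%dM", a, b)
          )),
          seq = rep(full, each = 2),
          sample_id = sid,
          tags = as.vector(rbind(
            sprintf("SA:Z:%s,%d,+,%dS%dM,60,0;", ci$chrom, pos2 + 1L, a, b),
            sprintf("SA:Z:%s,%d,+,%dM%dS,60,0;", ci$chrom, pos1 + 1L, a, b)
          ))
        )
      }
      # linear pool: canonical junction reads + exon-body reads over the sites
      o1 <- min(75L, ci$a_end - ci$a_start)
      o2 <- min(75L, ci$b_end - ci$b_start)
      jp1 <- edit_strings(
        rep(.block_seq(cseq, ci$a_end - o1, ci$a_end), n_lin),
        ci$a_end - o1, sites, profile$linear_editing_rate
      )
      jp2 <- edit_strings(
        rep(.block_seq(cseq, ci$b_start, ci$b_start + o2), n_lin),
        ci$b_start, sites, profile$linear_editing_rate
      )
      rec[[length(rec) + 1L]] <- tibble::tibble(
        qname = sprintf("lin:%s:%s:j%d", ci$gene_id, sid, seq_len(n_lin)),
        flag = 0L, chrom = ci$chrom, pos = ci$a_end - o1, mapq = 60L,
        cigar = sprintf("%dM%dN%dM", o1, ci$b_start - ci$a_end, o2),
        seq = .apply_errors(paste0(jp1, jp2), profile$error_rate),
        sample_id = sid, tags = ""
      )
      # exon-body reads over the exon carrying the editing sites (sense
      # exon 2: the reference-earlier exon on '+', reference-later on '-')
      body_start <- if (ci$strand == "+") ci$a_start else ci$b_end - 150L
      bseq0 <- .block_seq(cseq, body_start, body_start + 150L)
      bodies <- edit_strings(
        rep(bseq0, n_lin), body_start, sites,
        profile$linear_editing_rate
      )
      rec[[length(rec) + 1L]] <- tibble::tibble(
        qname = sprintf("lin:%s:%s:b%d", ci$gene_id, sid, seq_len(n_lin)),
        flag = 0L, chrom = ci$chrom, pos = body_start, mapq = 60L,
        cigar = "150M",
        seq = .apply_errors(bodies, profile$error_rate),
        sample_id = sid, tags = ""
      )
      truth[[length(truth) + 1L]] <- tibble::tibble(
        gene_id = ci$gene_id, chrom = ci$chrom, sample_id = sid, stage = stg,
        acceptor = ci$a_start, donor = ci$b_end,
        n_circ = n_circ, n_linear = n_lin,
        true_circ_fraction = profile$circ_fraction * mult
      )
      if (length(sites) > 0) {
        site_truth[[length(site_truth) + 1L]] <- tibble::tibble(
          gene_id = ci$gene_id, chrom = ci$chrom, pos = sites,
          sample_id = sid, stage = stg,
          circ_rate = circ_rate, linear_rate = profile$linear_editing_rate
        )
      }
    }
  }
  list(
    records = dplyr::bind_rows(rec),
    truth = dplyr::bind_rows(truth),
    site_truth = dplyr::bind_rows(site_truth)
  )
}

#' Write a complete synthetic dataset to a directory
#'
#' Emits `genome.fa`, `models.gtf`, `alu.bed`, `design.tsv`, one SAM per
#' sample and library type (`short_<sample>.sam`, `long_<sample>.sam`,
#' `circ_<sample>.sam`) and truth tables under `truth/`. Each output unit
#' draws from its own seeded stream (`seed + file index`), so regenerating
#' one component does not perturb the others.
#'
#' @param outdir Output directory (created if needed).
#' @param design A [stage_design()] tibble.
#' @param profile A [simulation_profile()].
#' @return Invisibly, a list with the simulation objects and file paths.
#' @export
simulate_dataset <- function(outdir, design = stage_design(),
                             profile = simulation_profile()) {
  dir.create(file.path(outdir, "truth"), recursive = TRUE, showWarnings = FALSE)
  sim <- generate_gene_models(profile$n_genes, seed = profile$seed)
  seqlens <- stats::setNames(
    Biostrings::width(sim$genome), names(sim$genome)
  )
  write_sequences(sim$genome, file.path(outdir, "genome.fa"))
  write_gene_models(sim$models, file.path(outdir, "models.gtf"))
  write_intervals(sim$alu, file.path(outdir, "alu.bed"))
  readr::write_tsv(design, file.path(outdir, "design.tsv"))

  short <- simulate_short_reads(sim, design, profile)
  long <- simulate_long_reads(sim, design, profile)
  circ <- simulate_circ_reads(sim, design, profile)
  for (sid in design$sample_id) {
    write_sam(
      short$records[short$records$sample_id == sid, ], seqlens,
      file.path(outdir, sprintf("short_%s.sam", sid))
    )
    write_sam(
      long$records[long$records$sample_id == sid, ], seqlens,
      file.path(outdir, sprintf("long_%s.sam", sid))
    )
    write_sam(
      circ$records[circ$records$sample_id == sid, ], seqlens,
      file.path(outdir, sprintf("circ_%s.sam", sid))
    )
  }
  readr::write_tsv(short$truth, file.path(outdir, "truth", "short.tsv"))
  readr::write_tsv(long$truth, file.path(outdir, "truth", "long.tsv"))
  readr::write_tsv(circ$truth, file.path(outdir, "truth", "circ.tsv"))
  readr::write_tsv(circ$site_truth, file.path(outdir, "truth", "edit_sites.tsv"))
  readr::write_tsv(sim$retained, file.path(outdir, "truth", "retained.tsv"))
  invisible(list(
    sim = sim, design = design, profile = profile, outdir = outdir,
    short = short, long = long, circ = circ
  ))
}
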