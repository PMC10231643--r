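test_that("gene model generation is deterministic and structurally valid", {
  a <- generate_gene_models(4, seed = 42)
  b <- generate_gene_models(4, seed = 42)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$models$exons, b$models$exons)
  expect_identical(a$retained, b$retained)

  # every intron begins GT and ends AG on the gene strand
  genome <- as.character(a$genome)
  for (i in seq_len(nrow(a$models$introns))) {
    it <- a$models$introns[i, ]
    s <- substr(genome[[it$chrom]], it$start + 1L, it$end)
    if (it$strand == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    expect_equal(substr(s, 1, 2), "GT")
    expect_equal(substr(s, nchar(s) - 1, nchar(s)), "AG")
  }
})

test_that("generated structures agree with an independent GTF re-parse", {
  sim <- generate_gene_models(50, seed = 2)
  path <- tempfile(fileext = ".gtf")
  write_gene_models(sim$models, path)
  back <- read_gene_models(path) # independent parser (rtracklayer)
  expect_equal(nrow(back$exons), nrow(sim$models$exons))
  expect_equal(nrow(back$introns), nrow(sim$models$introns))
  expect_setequal(back$introns$intron_id, sim$models$introns$intron_id)
  # exon counts within the documented 3-8 range, intron lengths within 100-2000
  expect_true(all(back$transcripts$n_exons >= 3 & back$transcripts$n_exons <= 8))
  ilen <- back$introns$end - back$introns$start
  expect_true(all(ilen >= 100 & ilen <= 2000))
})

test_that("true PIR 0 yields no exon-intron or intron-body reads", {
  sim <- generate_gene_models(2, seed = 8)
  prof <- simulation_profile(
    n_genes = 2, read_depth = 60, seed = 8, error_rate = 0,
    pir_trend = function(g, s) 0
  )
  sr <- simulate_short_reads(sim, stage_design(c(0, 6)), prof)
  expect_true(all(sr$truth$n_ei5 == 0 & sr$truth$n_ei3 == 0 & sr$truth$n_body == 0))
  expect_false(any(grepl(":ei[53]:|:bd:", sr$records$qname)))
})

test_that("empirical junction mix recovers true PIR at high depth", {
  sim <- generate_gene_models(1, seed = 4)
  prof <- simulation_profile(
    n_genes = 1, read_depth = 10000, seed = 4, error_rate = 0,
    pir_trend = function(g, s) 0.5
  )
  tr <- simulate_short_reads(sim, stage_design(), prof,
    emit_reads = FALSE
  )$truth
  ret <- tr[tr$true_pir > 0, ]
  # pooled over the 7 samples: x ~ Bin(N, q), q = 2p/(1+p), PIR = x/(2N - x)
  x <- sum(ret$n_ei5 + ret$n_ei3)
  N <- sum(ret$n_ee) + x
  pir_hat <- (x / 2) / (N - x + x / 2)
  # delta-method 3 SD of the pooled estimator at p = 0.5, N = 70,000
  expect_lt(abs(pir_hat - 0.5), 0.006)
})

test_that("short-read output is byte-identical under a fixed seed", {
  dir1 <- tempfile()
  dir2 <- tempfile()
  design <- stage_design(c(0, 3, 6))
  prof <- simulation_profile(n_genes = 2, read_depth = 30, long_read_depth = 8, seed = 9)
  simulate_dataset(dir1, design, prof)
  simulate_dataset(dir2, design, prof)
  for (f in list.files(dir1, pattern = "\\.(sam|fa|gtf|bed)$")) {
    expect_identical(
      readLines(file.path(dir1, f)), readLines(file.path(dir2, f)),
      info = f
    )
  }
})

test_that("long reads retain the designated intron at the true PIR", {
  sim <- generate_gene_models(1, seed = 6)
  design <- stage_design(c(0, 6))
  # PIR 1: every long read carries the intron as one contiguous block
  prof1 <- simulation_profile(
    n_genes = 1, read_depth = 30, long_read_depth = 12, seed = 6,
    error_rate = 0, pir_trend = function(g, s) 1
  )
  lr <- simulate_long_reads(sim, design, prof1)
  expect_true(all(lr$truth$n_retained == lr$truth$n_reads))
  pl <- parse_records(
    lr$records[lr$records$sample_id == design$sample_id[1], ],
    setNames(Biostrings::width(sim$genome), names(sim$genome))
  )
  ret <- sim$retained
  for (rid in unique(pl$read_id)) {
    b <- pl[pl$read_id == rid, ]
    expect_true(any(b$start <= ret$start - 1 & b$end >= ret$end + 1), info = rid)
    expect_true(all(b$polyA))
  }

  # retention fraction tracks PIR at depth 5,000 (binomial 3 SD)
  prof2 <- simulation_profile(
    n_genes = 1, read_depth = 30, long_read_depth = 5000, seed = 7,
    error_rate = 0, pir_trend = function(g, s) 0.3
  )
  tr <- simulate_long_reads(sim, design, prof2)$truth
  frac <- tr$n_retained / tr$n_reads
  expect_true(all(abs(frac - 0.3) < 3 * sqrt(0.3 * 0.7 / 5000)))
})

test_that("truth-table counts equal emitted read counts", {
  sim <- generate_gene_models(3, seed = 10)
  design <- stage_design(c(0, 3, 6))
  prof <- simulation_profile(n_genes = 3, read_depth = 50, seed = 10)
  sr <- simulate_short_reads(sim, design, prof)
  # qname layout: sr:gene:intron:sample:kind:i
  emitted <- sr$records |>
    tidyr::separate_wider_delim(qname,
      delim = ":",
      names = c("pref", "gene", "tx_i", "intron_i", "sid", "kind", "i")
    ) |>
    dplyr::mutate(intron_id = paste(tx_i, intron_i, sep = ":")) |>
    dplyr::count(intron_id, sample_id, kind)
  truth_long <- sr$truth |>
    tidyr::pivot_longer(c(n_ee, n_ei5, n_ei3, n_body),
      names_to = "kind", values_to = "n"
    ) |>
    dplyr::mutate(kind = c(
      n_ee = "ee", n_ei5 = "ei5", n_ei3 = "ei3",
      n_body = "bd"
    )[kind]) |>
    dplyr::filter(n > 0)
  joined <- dplyr::inner_join(truth_long, emitted,
    by = c("intron_id", "sample_id", "kind")
  )
  expect_equal(nrow(joined), nrow(truth_long))
  expect_equal(joined$n.x, joined$n.y)
})

test_that("circular reads carry no A>G changes when editing and error are zero", {
  sim <- generate_gene_models(2, seed = 12)
  design <- stage_design(c(0, 6))
  prof <- simulation_profile(
    n_genes = 2, read_depth = 80, rnase_r_enrichment = 100, seed = 12,
    error_rate = 0, linear_editing_rate = 0,
    editing_trend = function(s) 0
  )
  cr <- simulate_circ_reads(sim, design, prof)
  seqlens <- setNames(Biostrings::width(sim$genome), names(sim$genome))
  pl <- parse_records(cr$records[cr$records$sample_id == design$sample_id[1], ],
    sample_id = design$sample_id[1], seqlens
  )
  pile <- pileup_editing(pl, sim$genome, sim$models)
  expect_true(all(pile$g_count == 0))
})

test_that("circular/linear read ratio matches circ_fraction with a flat multiplier", {
  sim <- generate_gene_models(4, seed = 13)
  design <- stage_design()
  prof <- simulation_profile(
    n_genes = 4, read_depth = 400, circ_fraction = 0.01,
    rnase_r_enrichment = 1, seed = 13,
    circ_stage_multiplier = function(g, s) 1
  )
  tr <- simulate_circ_reads(sim, design, prof)$truth
  total_circ <- sum(tr$n_circ)
  total_lin <- sum(tr$n_linear)
  ratio <- total_circ / total_lin
  se <- sqrt(total_circ) / total_lin
  expect_lt(abs(ratio - 0.01), 3 * se + 1e-4)
})
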