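test_that("junction classification follows the boundary rules", {
  models <- two_exon_models() # intron (200, 300)
  pl <- make_placements(tibble::tibble(
    read_id = c("ee", "ee", "ei5", "ei3", "bd", "short5"),
    start = c(180L, 300L, 190L, 292L, 210L, 195L),
    end = c(200L, 320L, 210L, 312L, 280L, 205L)
  ))
  cnt <- count_junction_reads(pl, models, min_overhang = 8L)
  expect_equal(cnt$EE, 1L) # blocks abut the intron exactly
  expect_equal(cnt$EI5, 1L) # 10 bases each side of the 5' boundary
  expect_equal(cnt$EI3, 1L)
  expect_equal(cnt$body, 1L)
  # "short5" has only 5 bases beyond the boundary: below min_overhang
  expect_equal(cnt$EE + cnt$EI5 + cnt$EI3 + cnt$body, 4L)
})

test_that("a read crossing the whole intron increments one counter only", {
  models <- two_exon_models()
  pl <- make_placements(tibble::tibble(
    read_id = "span", start = 150L, end = 350L
  ))
  cnt <- count_junction_reads(pl, models)
  expect_equal(cnt$EI5 + cnt$EI3, 1L)
  expect_equal(cnt$EE, 0L)
})

test_that("PIR follows the averaged-numerator formula", {
  base <- tibble::tibble(
    intron_id = "i", sample_id = "s", body = 0L,
    body_coverage_fraction = 0
  )
  expect_equal(compute_pir(dplyr::mutate(base, EE = 100L, EI5 = 0L, EI3 = 0L))$PIR, 0)
  expect_equal(compute_pir(dplyr::mutate(base, EE = 50L, EI5 = 50L, EI3 = 50L))$PIR, 50)
  expect_true(is.na(compute_pir(dplyr::mutate(base, EE = 0L, EI5 = 0L, EI3 = 0L))$PIR))
  expect_error(compute_pir(dplyr::mutate(base, EE = -1L, EI5 = 0L, EI3 = 0L)), "negative")

  # random grids equal an independent recomputation, and PIR is monotone in EI
  set.seed(1)
  grid <- tibble::tibble(
    intron_id = sprintf("i%d", 1:300), sample_id = "s",
    EE = rpois(300, 40), EI5 = rpois(300, 15), EI3 = rpois(300, 15),
    body = 0L, body_coverage_fraction = 0
  )
  got <- compute_pir(grid)$PIR
  oracle <- with(grid, {
    ei <- (EI5 + EI3) / 2
    ifelse(EE + ei > 0, 100 * ei / (EE + ei), NA_real_)
  })
  expect_equal(got, oracle)
  expect_true(all(got >= 0 & got <= 100, na.rm = TRUE))
  fixed_ee <- function(ei) compute_pir(dplyr::mutate(base, EE = 30L, EI5 = ei, EI3 = ei))$PIR
  pirs <- vapply(c(1L, 5L, 10L, 40L), fixed_ee, numeric(1))
  expect_true(all(diff(pirs) > 0))
})

test_that("detection thresholds gate on both boundaries, body and total", {
  base <- tibble::tibble(
    intron_id = "i", sample_id = "s", EE = 50L,
    body = 10L, body_coverage_fraction = 0.9
  )
  det <- function(...) {
    detect_retained_introns(compute_pir(dplyr::mutate(base, ...)))$detected
  }
  expect_false(det(EI5 = 0L, EI3 = 0L))
  expect_false(det(EI5 = 1L, EI3 = 5L)) # 5' boundary below min_ei
  expect_true(det(EI5 = 2L, EI3 = 2L))
  # body coverage below threshold blocks detection
  low_cov <- dplyr::mutate(base,
    EI5 = 5L, EI3 = 5L,
    body_coverage_fraction = 0.2
  )
  expect_false(detect_retained_introns(compute_pir(low_cov))$detected)
})

test_that("junction counts on generator reads equal the truth table", {
  sim <- generate_gene_models(3, seed = 21)
  design <- stage_design(c(0, 6))
  prof <- simulation_profile(
    n_genes = 3, read_depth = 120, seed = 21,
    error_rate = 0, pir_trend = function(g, s) 0.3
  )
  sr <- simulate_short_reads(sim, design, prof)
  seqlens <- setNames(Biostrings::width(sim$genome), names(sim$genome))
  for (sid in design$sample_id) {
    pl <- parse_records(sr$records[sr$records$sample_id == sid, ], seqlens,
      sample_id = sid
    )
    cnt <- count_junction_reads(pl, sim$models)
    tr <- sr$truth[sr$truth$sample_id == sid, ]
    j <- dplyr::inner_join(cnt, tr, by = "intron_id")
    expect_equal(nrow(j), nrow(tr))
    expect_equal(j$EE, j$n_ee)
    expect_equal(j$EI5, j$n_ei5)
    expect_equal(j$EI3, j$n_ei3)
    expect_equal(j$body, j$n_body)
  }
})

test_that("detection recall and precision reach 0.95 on error-free truth", {
  sim <- generate_gene_models(3, seed = 31)
  design <- stage_design(c(0, 6))
  prof <- simulation_profile(
    n_genes = 3, read_depth = 2000, seed = 31,
    error_rate = 0, pir_trend = function(g, s) 0.3
  )
  sr <- simulate_short_reads(sim, design, prof)
  seqlens <- setNames(Biostrings::width(sim$genome), names(sim$genome))
  truth_pos <- sim$retained$intron_id
  for (sid in design$sample_id) {
    pl <- parse_records(sr$records[sr$records$sample_id == sid, ], seqlens,
      sample_id = sid
    )
    det <- detect_retained_introns(compute_pir(count_junction_reads(pl, sim$models)))
    called <- det$intron_id[det$detected]
    recall <- length(intersect(called, truth_pos)) / length(truth_pos)
    precision <- if (length(called) > 0) {
      length(intersect(called, truth_pos)) / length(called)
    } else {
      1
    }
    expect_gte(recall, 0.95)
    expect_gte(precision, 0.95)
  }
})

test_that("long-read validation applies the strict >10 rule", {
  sim <- generate_gene_models(3, seed = 41)
  design <- stage_design(c(0, 6))
  # per-gene long-read counts 5, 11, 40 with full retention: only genes with
  # more than 10 supporting reads validate (one sample, so counts are exact)
  design1 <- stage_design(c(0, 6))
  prof <- simulation_profile(
    n_genes = 3, read_depth = 30, seed = 41, error_rate = 0,
    long_read_depth = c(5, 11, 40),
    pir_trend = function(g, s) 1
  )
  lr <- simulate_long_reads(sim, design1, prof)
  seqlens <- setNames(Biostrings::width(sim$genome), names(sim$genome))
  sid <- design1$sample_id[1]
  pl <- parse_records(lr$records[lr$records$sample_id == sid, ], seqlens,
    sample_id = sid
  )
  got <- validate_with_long_reads(sim$retained$intron_id, pl, sim$models,
    min_reads = 10L
  )
  support <- attr(got, "support")
  expect_equal(unname(support[sim$retained$intron_id]), c(5L, 11L, 40L))
  expect_setequal(got, sim$retained$intron_id[c(2, 3)])

  # exactly 10 reads: NOT validated; 11: validated
  prof2 <- simulation_profile(
    n_genes = 3, read_depth = 30, seed = 42, error_rate = 0,
    long_read_depth = c(10, 11, 3), pir_trend = function(g, s) 1
  )
  lr2 <- simulate_long_reads(sim, design1, prof2)
  pl2 <- parse_records(lr2$records[lr2$records$sample_id == sid, ], seqlens,
    sample_id = sid
  )
  got2 <- validate_with_long_reads(sim$retained$intron_id, pl2, sim$models)
  expect_false(sim$retained$intron_id[1] %in% got2)
  expect_true(sim$retained$intron_id[2] %in% got2)
})

test_that("stage correlation matches a rank-then-Pearson oracle", {
  design <- stage_design()
  vals <- tibble::tibble(
    feature_id = "f", sample_id = design$sample_id,
    value = c(1, 2, 3, 4, 5, 6, 7)
  )
  expect_equal(correlate_with_stage(vals, design)$rho, 1)

  const <- dplyr::mutate(vals, value = 5)
  out <- correlate_with_stage(const, design)
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "skipped"), "f")

  set.seed(7)
  for (i in 1:25) {
    v <- rnorm(7)
    tbl <- tibble::tibble(feature_id = "f", sample_id = design$sample_id, value = v)
    got <- correlate_with_stage(tbl, design)$rho
    oracle <- stats::cor(rank(v), rank(design$stage))
    expect_equal(got, oracle, tolerance = 1e-12)
  }
})

test_that("stage-trending PIR separates from flat PIR over 20 seeds", {
  design <- stage_design()
  trend_pass <- 0L
  trend_total <- 0L
  flat_fail <- 0L
  flat_total <- 0L
  for (seed in 1:20) {
    sim <- generate_gene_models(10, seed = seed)
    prof <- simulation_profile(
      n_genes = 10, read_depth = 2000, seed = seed, error_rate = 0
    )
    tr <- simulate_short_reads(sim, design, prof, emit_reads = FALSE)$truth
    counts <- tr |>
      dplyr::semi_join(sim$retained, by = "intron_id") |>
      dplyr::transmute(intron_id, sample_id,
        EE = n_ee, EI5 = n_ei5, EI3 = n_ei3,
        body = n_body, body_coverage_fraction = 1
      )
    pir <- compute_pir(counts)
    corr <- correlate_with_stage(
      dplyr::transmute(pir,
        feature_id = intron_id, sample_id = sample_id,
        value = PIR
      ), design
    )
    ret <- sim$retained
    trend_ids <- ret$intron_id[seq_len(nrow(ret)) %% 2 == 1]
    flat_ids <- setdiff(ret$intron_id, trend_ids)
    trend_pass <- trend_pass + sum(corr$passes[corr$feature_id %in% trend_ids])
    trend_total <- trend_total + length(trend_ids)
    flat_fail <- flat_fail +
      sum(!corr$passes[corr$feature_id %in% flat_ids]) +
      sum(!flat_ids %in% corr$feature_id)
    flat_total <- flat_total + length(flat_ids)
  }
  expect_gte(trend_pass / trend_total, 0.90)
  expect_gte(flat_fail / flat_total, 0.95)
})

test_that("count totals never exceed reads attributed to a gene", {
  sim <- generate_gene_models(2, seed = 51)
  design <- stage_design(c(0, 6))
  prof <- simulation_profile(n_genes = 2, read_depth = 80, seed = 51)
  sr <- simulate_short_reads(sim, design, prof)
  seqlens <- setNames(Biostrings::width(sim$genome), names(sim$genome))
  sid <- design$sample_id[2]
  pl <- parse_records(sr$records[sr$records$sample_id == sid, ], seqlens,
    sample_id = sid
  )
  cnt <- count_junction_reads(pl, sim$models)
  per_gene <- dplyr::left_join(cnt,
    dplyr::select(sim$models$introns, intron_id, gene_id),
    by = "intron_id"
  ) |>
    dplyr::group_by(gene_id) |>
    dplyr::summarise(total = sum(EE + EI5 + EI3 + body))
  reads_per_gene <- pl |>
    dplyr::distinct(read_id, chrom) |>
    dplyr::count(chrom)
  m <- match(sim$models$transcripts$gene_id, per_gene$gene_id)
  expect_true(all(
    per_gene$total[m] <=
      reads_per_gene$n[match(sim$models$transcripts$chrom, reads_per_gene$chrom)]
  ))
})
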