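# models with exons (100,200), (300,400), (500,600): a circle over exons
# 2-3 has acceptor 300 and donor 600
circ_models <- function() {
  gene_models(tibble::tibble(
    gene_id = "gA", transcript_id = "tA", chrom = "c1", strand = "+",
    start = c(100L, 300L, 500L), end = c(200L, 400L, 600L)
  ))
}

bsj_read <- function(id, sample_id = "s1") {
  make_placements(
    tibble::tibble(
      read_id = id,
      start = c(300L, 560L), end = c(340L, 600L),
      query_order = c(1L, 0L), # genomic order inverted vs query order
      is_supplementary_pair = TRUE
    ),
    sample_id = sample_id
  )
}

test_that("inverted split reads at annotated splice sites define one BSJ", {
  pl <- dplyr::bind_rows(bsj_read("r1"), bsj_read("r2"))
  bsj <- detect_bsj(pl, circ_models())
  expect_equal(nrow(bsj), 1L)
  expect_equal(bsj$bsj_start, 300L)
  expect_equal(bsj$bsj_end, 600L)
  expect_equal(bsj$count, 2L)
  expect_equal(bsj$bsj_id, "c1:300|600")
})

test_that("colinear spliced reads never support a BSJ", {
  pl <- make_placements(tibble::tibble(
    read_id = c("r1", "r1"), start = c(180L, 300L), end = c(200L, 340L)
  ))
  expect_equal(nrow(detect_bsj(pl, circ_models())), 0L)
})

test_that("min_support and min_seg gate BSJ reporting", {
  one <- bsj_read("r1")
  expect_equal(nrow(detect_bsj(one, circ_models(), min_support = 2L)), 0L)
  expect_equal(nrow(detect_bsj(one, circ_models(), min_support = 1L)), 1L)
  # a 10-base segment is below min_seg
  short <- make_placements(
    tibble::tibble(
      read_id = "r1", start = c(300L, 590L), end = c(340L, 600L),
      query_order = c(1L, 0L), is_supplementary_pair = TRUE
    )
  )
  expect_equal(nrow(detect_bsj(short, circ_models(), min_support = 1L)), 0L)
})

test_that("generator back-splice reads are recovered with exact counts", {
  sim <- generate_gene_models(3, seed = 81)
  design <- stage_design(c(0, 3, 6))
  prof <- simulation_profile(
    n_genes = 3, read_depth = 100, rnase_r_enrichment = 40,
    seed = 81, error_rate = 0
  )
  cr <- simulate_circ_reads(sim, design, prof)
  seqlens <- setNames(Biostrings::width(sim$genome), names(sim$genome))
  pl <- dplyr::bind_rows(lapply(design$sample_id, function(sid) {
    parse_records(cr$records[cr$records$sample_id == sid, ], seqlens,
      sample_id = sid
    )
  }))
  bsj <- detect_bsj(pl, sim$models, min_support = 1L)
  truth <- cr$truth[cr$truth$n_circ > 0, ]
  got <- dplyr::inner_join(
    bsj, truth,
    by = dplyr::join_by(gene_id, sample_id, bsj_start == acceptor, bsj_end == donor)
  )
  expect_equal(nrow(got), nrow(truth))
  expect_equal(got$count, got$n_circ)
  # every reported BSJ is supported and keyed by annotated splice sites
  expect_true(all(bsj$count >= 1))
  expect_true(all(bsj$bsj_start %in% sim$models$exons$start))
  expect_true(all(bsj$bsj_end %in% sim$models$exons$end))
})

test_that("junction ratio is the circular fraction of local reads", {
  bsj <- tibble::tibble(
    bsj_id = "c1:300|600", chrom = "c1", bsj_start = 300L, bsj_end = 600L,
    gene_id = "gA", sample_id = "s1", count = 10L
  )
  lin <- tibble::tibble(gene_id = "gA", sample_id = "s1", linear_count = 990L)
  q <- quantify_normalize(bsj, lin)
  expect_equal(q$junction_ratio, 10 / 1000)

  # scale invariance: doubling all counts in the sample leaves the ratio
  q2 <- quantify_normalize(
    dplyr::mutate(bsj, count = 20L),
    dplyr::mutate(lin, linear_count = 1980L)
  )
  expect_equal(q2$junction_ratio, q$junction_ratio)
})

test_that("mean junction ratio recovers circ_fraction on generator data", {
  sim <- generate_gene_models(4, seed = 91)
  design <- stage_design()
  prof <- simulation_profile(
    n_genes = 4, read_depth = 400, circ_fraction = 0.01,
    rnase_r_enrichment = 1, seed = 91, error_rate = 0,
    circ_stage_multiplier = function(g, s) 1
  )
  cr <- simulate_circ_reads(sim, design, prof)
  seqlens <- setNames(Biostrings::width(sim$genome), names(sim$genome))
  pl <- dplyr::bind_rows(lapply(design$sample_id, function(sid) {
    parse_records(cr$records[cr$records$sample_id == sid, ], seqlens,
      sample_id = sid
    )
  }))
  bsj <- detect_bsj(pl, sim$models, min_support = 1L)
  lin <- cr$truth |>
    dplyr::select(gene_id, sample_id, linear_count = n_linear)
  q <- quantify_normalize(bsj, lin)
  total_c <- sum(q$count)
  total_l <- sum(dplyr::distinct(q, gene_id, sample_id, linear_count)$linear_count)
  ratio <- total_c / (total_c + total_l)
  se <- sqrt(total_c) / total_l
  expect_lt(abs(ratio - 0.01), 3 * se + 1e-4)
})

test_that("stage-regulated circRNAs are called by the FC-and-p rule", {
  design <- stage_design()
  mk_norm <- function(vals_by_feature) {
    purrr::imap(vals_by_feature, function(v, id) {
      tibble::tibble(
        bsj_id = id, chrom = "c1", gene_id = "g", sample_id = design$sample_id,
        count = 0L, linear_count = 0L, junction_ratio = NA_real_,
        norm_expr = v
      )
    }) |> dplyr::bind_rows()
  }
  flat <- mk_norm(list(f1 = rep(5, 7), f2 = rep(2, 7)))
  res <- call_regulated_circ(flat, design)
  expect_equal(res$n_regulated, 0L)

  up4 <- mk_norm(list(
    f1 = c(5, 5.1, 5, 5, 5, 20, 20.4), # 4x in stages 5+6 vs 0+1
    f2 = rep(3, 7)
  ))
  res2 <- call_regulated_circ(up4, design)
  expect_true("f1" %in% res2$up)
  expect_false("f2" %in% c(res2$up, res2$down))

  # fold change 1.4 is never regulated, however small the p-value
  fc14 <- mk_norm(list(f1 = c(10, 10.01, 10, 10, 10, 14, 14.01), f2 = rep(3, 7)))
  res3 <- call_regulated_circ(fc14, design)
  ct <- res3$contrasts[res3$contrasts$feature_id == "f1", ]
  expect_lt(ct$fold_change, 1.5)
  expect_false(ct$regulated)
})

test_that("ranking against a reference uses dense descending ranks", {
  design <- stage_design(c(0, 6))
  norm <- purrr::imap(
    list(a = 5, b = 4, c = 3, d = 2, e = 1),
    function(v, id) {
      tibble::tibble(
        bsj_id = id, chrom = "c1", gene_id = paste0("g_", id),
        sample_id = design$sample_id, count = 0L, linear_count = 0L,
        junction_ratio = NA_real_, norm_expr = v
      )
    }
  ) |> dplyr::bind_rows()
  rk <- rank_vs_reference(norm, "c")
  expect_setequal(rk$above_reference, c("a", "b"))
  expect_equal(rk$ranks$circ_rank, 1:5)

  # reference at the maximum: nothing above
  expect_equal(length(rank_vs_reference(norm, "a")$above_reference), 0L)
  expect_error(rank_vs_reference(norm, "zz"), "not found")

  # ties share the smaller rank (dense), checked against a sort oracle
  norm_t <- dplyr::mutate(norm, norm_expr = c(5, 5, 3, 3, 1)[match(bsj_id, letters[1:5])])
  rk_t <- rank_vs_reference(norm_t, "e")$ranks
  means <- tapply(norm_t$norm_expr, norm_t$bsj_id, mean)
  oracle <- match(-means, sort(unique(-means)))
  expect_equal(rk_t$circ_rank[match(names(means), rk_t$bsj_id)], oracle)
})

test_that("stage-trending circRNA matrices cluster by stage", {
  design <- stage_design()
  ok <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    m <- sapply(design$stage, function(s) (1 + s / 2) * exp(rnorm(30, sd = 0.15)))
    colnames(m) <- design$sample_id
    ord <- match(cluster_samples(log2(m))$order, design$sample_id)
    stages <- design$stage[ord]
    if (all(diff(stages) > 0) || all(diff(stages) < 0)) ok <- ok + 1L
  }
  expect_gte(ok / 20, 0.90)
})
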