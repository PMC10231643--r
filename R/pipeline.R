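# End-to-end orchestration: simulate -> detect -> quantify -> correlate ->
# report, from a single YAML config.

.default_config <- function() {
  list(
    outdir = NULL,
    seed = 1L,
    design = list(stages = 0:6),
    profile = list(
      n_genes = 8L, read_depth = 150L, long_read_depth = 30L,
      circ_fraction = 0.01, rnase_r_enrichment = 40,
      error_rate = 0.001, linear_editing_rate = 0.02
    ),
    thresholds = list(
      min_overhang = 8L, min_ei = 2L, min_body = 0.5, min_total = 10L,
      min_long_reads = 10L, rho_threshold = 0.8,
      bsj_tol = 2L, bsj_min_seg = 15L, bsj_min_support = 2L,
      edit_min_depth = 5L, edit_min_g = 2L, edge_buffer = 3L
    )
  )
}

#' Validate and complete a pipeline configuration
#'
#' @param config A list or path to a YAML file. Unknown keys are rejected;
#'   missing keys take the documented defaults.
#' @return The completed config list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  def <- .default_config()
  bad <- setdiff(names(config), names(def))
  if (length(bad) > 0) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  }
  for (sec in c("design", "profile", "thresholds")) {
    if (!is.null(config[[sec]])) {
      bad <- setdiff(names(config[[sec]]), names(def[[sec]]))
      if (length(bad) > 0) {
        stop("unknown config key(s): ", paste(paste0(sec, ".", bad), collapse = ", "))
      }
      def[[sec]] <- utils::modifyList(def[[sec]], config[[sec]])
    }
  }
  for (k in setdiff(names(config), c("design", "profile", "thresholds"))) {
    def[[k]] <- config[[k]]
  }
  if (is.null(def$outdir)) stop("config must set outdir")
  def
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes, in dependency order: synthetic-data generation, alignment
#' parsing, intron-retention quantification (junction counts, PIR,
#' detection, stage correlation, long-read validation), circRNA detection
#' and quantification with stage-regulated calling, editing pileup/index/
#' trend, and a machine-readable report. Intermediate tables are written as
#' TSV under `outdir`; the report as `report.json`. Every number in the
#' report is re-derivable from the emitted TSVs.
#'
#' @param config A config list or YAML path (see [pipeline_config()]).
#' @param stages Character subset of
#'   `c("simulate", "intron", "circ", "editing", "report")` to run; later
#'   stages require the files earlier stages write and fail with a named
#'   stage otherwise.
#' @return The report, invisibly also written to `outdir/report.json`.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "intron", "circ", "editing", "report")) {
  cfg <- pipeline_config(config)
  out <- cfg$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  design <- stage_design(cfg$design$stages)
  profile <- do.call(simulation_profile, c(cfg$profile, list(seed = cfg$seed)))
  th <- cfg$thresholds
  log_lines <- character()
  note <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    log_lines <<- c(log_lines, line)
    message(line)
  }

  if ("simulate" %in% stages) {
    .stage("simulate", {
      simulate_dataset(out, design, profile)
      note("simulate: %d genes, %d samples", profile$n_genes, nrow(design))
    })
  }

  need <- function(stage, path) {
    if (!file.exists(path)) {
      stop("pipeline stage '", stage, "' failed: missing input ", path, call. = FALSE)
    }
    path
  }

  report <- list(
    version = as.character(utils::packageVersion("circintron")),
    config_hash = rlang::hash(cfg[setdiff(names(cfg), "outdir")]),
    thresholds = th
  )

  if ("intron" %in% stages) {
    .stage("intron", {
      models <- read_gene_models(need("intron", file.path(out, "models.gtf")))
      counts <- dplyr::bind_rows(lapply(design$sample_id, function(sid) {
        pl <- read_spliced_alignments(
          need("intron", file.path(out, sprintf("short_%s.sam", sid))), sid
        )
        count_junction_reads(pl, models, min_overhang = th$min_overhang)
      }))
      pir <- compute_pir(counts)
      det <- detect_retained_introns(pir, models,
        min_ei = th$min_ei,
        min_body = th$min_body, min_total = th$min_total
      )
      readr::write_tsv(det, file.path(out, "pir.tsv"))
      corr <- correlate_with_stage(
        dplyr::transmute(pir,
          feature_id = .data$intron_id,
          sample_id = .data$sample_id, value = .data$PIR
        ),
        design,
        threshold = th$rho_threshold
      )
      readr::write_tsv(corr, file.path(out, "pir_stage_correlation.tsv"))
      long_pl <- dplyr::bind_rows(lapply(design$sample_id, function(sid) {
        read_spliced_alignments(
          need("intron", file.path(out, sprintf("long_%s.sam", sid))), sid
        )
      }))
      detected_any <- unique(det$intron_id[det$detected])
      validated <- validate_with_long_reads(detected_any, long_pl, models,
        min_reads = th$min_long_reads
      )
      support_all <- attr(
        validate_with_long_reads(
          unique(det$intron_id), long_pl, models, th$min_long_reads
        ),
        "support"
      )
      correlated <- corr$feature_id[corr$passes]
      with_cov <- correlated[support_all[correlated] >= 1 &
        !is.na(support_all[correlated])]
      val_and_corr <- intersect(
        correlated,
        names(support_all)[support_all > th$min_long_reads]
      )
      validated_tbl <- models$introns[models$introns$intron_id %in% validated, ]
      write_intervals(
        dplyr::transmute(validated_tbl, .data$chrom, .data$start, .data$end,
          label = .data$intron_id, score = 0, strand = .data$strand
        ),
        file.path(out, "validated_introns.bed")
      )
      report$intron <- list(
        n_introns = length(unique(det$intron_id)),
        n_detected_any_sample = length(detected_any),
        n_validated = length(validated),
        n_stage_correlated = length(correlated),
        n_correlated_with_coverage = length(with_cov),
        n_validated_and_correlated = length(val_and_corr),
        validation_rate_pct = if (length(with_cov) > 0) {
          round(100 * length(val_and_corr) / length(with_cov), 1)
        } else {
          NA_real_
        }
      )
      note(
        "intron: %d detected, %d validated, %d stage-correlated",
        length(detected_any), length(validated), length(correlated)
      )
    })
  }

  if ("circ" %in% stages) {
    .stage("circ", {
      models <- read_gene_models(need("circ", file.path(out, "models.gtf")))
      circ_pl <- dplyr::bind_rows(lapply(design$sample_id, function(sid) {
        read_spliced_alignments(
          need("circ", file.path(out, sprintf("circ_%s.sam", sid))), sid
        )
      }))
      bsj <- detect_bsj(circ_pl, models,
        tol = th$bsj_tol,
        min_seg = th$bsj_min_seg, min_support = th$bsj_min_support
      )
      # linear counts: canonical junction reads over each gene locus
      juncs <- splice_junctions(circ_pl[!circ_pl$is_supplementary_pair, ])
      lin <- juncs |>
        dplyr::inner_join(
          dplyr::select(models$introns, "chrom",
            junc_start = "start",
            junc_end = "end", "gene_id"
          ),
          by = c("chrom", "junc_start", "junc_end")
        ) |>
        dplyr::count(.data$gene_id, .data$sample_id, name = "linear_count")
      lin <- tidyr::complete(lin,
        gene_id = unique(models$transcripts$gene_id),
        sample_id = design$sample_id, fill = list(linear_count = 0L)
      )
      norm <- quantify_normalize(bsj, lin)
      readr::write_tsv(norm, file.path(out, "circ_quant.tsv"))
      called <- call_regulated_circ(norm, design)
      readr::write_tsv(called$contrasts, file.path(out, "circ_regulated.tsv"))
      report$circ <- list(
        n_bsj = length(unique(bsj$bsj_id)),
        mean_junction_ratio = mean(norm$junction_ratio, na.rm = TRUE),
        n_regulated = called$n_regulated,
        n_up = length(called$up), n_down = length(called$down)
      )
      note(
        "circ: %d BSJs, %d regulated", length(unique(bsj$bsj_id)),
        called$n_regulated
      )
    })
  }

  if ("editing" %in% stages) {
    .stage("editing", {
      models <- read_gene_models(need("editing", file.path(out, "models.gtf")))
      genome <- read_sequences(need("editing", file.path(out, "genome.fa")))
      pile <- dplyr::bind_rows(lapply(design$sample_id, function(sid) {
        pl <- read_spliced_alignments(
          need("editing", file.path(out, sprintf("circ_%s.sam", sid))), sid
        )
        pileup_editing(pl, genome, models, edge_buffer = th$edge_buffer)
      }))
      readr::write_tsv(pile, file.path(out, "editing_sites.tsv"))
      idx <- editing_index(pile,
        min_depth = th$edit_min_depth,
        min_g = th$edit_min_g
      )
      readr::write_tsv(idx, file.path(out, "editing_index.tsv"))
      trend <- editing_stage_trend(idx, design)
      readr::write_tsv(trend, file.path(out, "editing_trend.tsv"))
      report$editing <- list(
        circular_rho = trend$rho[trend$pool == "circular"],
        circular_r_squared = trend$r_squared[trend$pool == "circular"],
        linear_rho = trend$rho[trend$pool == "linear"]
      )
      note(
        "editing: circular rho %.2f, linear rho %.2f",
        report$editing$circular_rho, report$editing$linear_rho
      )
    })
  }

  if ("report" %in% stages) {
    .stage("report", {
      report$log <- log_lines
      jsonlite::write_json(report, file.path(out, "report.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE
      )
      note("report written to %s", file.path(out, "report.json"))
    })
  }
  invisible(report)
}
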