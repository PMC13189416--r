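#' Pipeline configuration with the analysis defaults
#'
#' Every numeric default traces to the analysis design: expression floor 5,
#' NMF stopping threshold 0.05 and default rank 10, rank sweep 2..15, top
#' four PCs with outlier threshold z > 2, 100 robustness restarts, top-500
#' gene lists with expression floor 3, DEG thresholds padj < 0.05 and
#' |log2FC| > 0.58, and TSS windows of +/-1 kb (proximal) and +/-50 kb
#' (distal).
#'
#' @param ... overrides of the listed defaults.
#' @return `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    expression = NULL, sample_sheet = NULL, peaks = NULL, tss = NULL,
    tf_list = NULL, de_tables = NULL,
    floor = 5, theta = 0.05, M = 10, M_range = 2:15, n_pcs = 4,
    z_threshold = 2, robustness_runs = 100, top_n = 500, expr_floor_go = 3,
    alpha = 0.05, lfc = 0.58, proximal = 1000, distal = 50000,
    background_floor = 5, seed = 20240101, excluded_timepoints = NULL)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

.manifest_add <- function(manifest, name, path) {
  manifest$artifacts[[name]] <- list(
    path = basename(path), md5 = unname(tools::md5sum(path)))
  manifest
}

#' Run one pipeline stage (or all of them)
#'
#' Stages: `simulate` (write the synthetic fixture), `normalize`
#' (size factors, filtering, replicate averaging, max scaling), `qc`
#' (PC z-score outlier report, timepoint correlations, dendrogram), `fit`
#' (NMF at the configured rank), `sweep` (rank selection), `robustness`
#' (restart analysis), `behaviors` (assignments, display order, top gene
#' lists), `enrich` (TSS-window binding enrichment of the top gene lists
#' and any supplied DEG tables), `all` (everything in order; simulates a
#' fixture when no expression input is configured). Artifacts and a
#' manifest (config echo, seed, checksums) are written to `outdir`.
#'
#' @param stage one of the stage names above.
#' @param config [pipeline_config()].
#' @param outdir output directory (created).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "normalize", "qc",
                                   "fit", "sweep", "robustness",
                                   "behaviors", "enrich"),
                         config = pipeline_config(), outdir = "tempoNMF_out") {
  stage <- match.arg(stage)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(stage = stage, seed = config$seed,
                   config = config[!vapply(config, is.null, logical(1))],
                   artifacts = list())
  stages <- if (stage == "all") {
    c(if (is.null(config$expression)) "simulate",
      "normalize", "qc", "fit", "sweep", "robustness", "behaviors",
      if (!is.null(config$peaks) || is.null(config$expression)) "enrich")
  } else stage

  if ("simulate" %in% stages) {
    ds <- default_fixture(seed = config$seed)
    paths <- write_synthetic_dataset(ds, outdir)
    toy <- make_peaks_and_annotation(nrow(ds$expression), 0.4, 0.1,
                                     seed = config$seed)
    write_peaks_bed(toy$peaks, file.path(outdir, "peaks.bed"))
    write_tss_table(toy$tss, file.path(outdir, "tss.tsv"))
    writeLines(toy$foreground, file.path(outdir, "foreground_genes.txt"))
    config$expression <- paths[["expression"]]
    config$sample_sheet <- paths[["sheet"]]
    config$peaks <- file.path(outdir, "peaks.bed")
    config$tss <- file.path(outdir, "tss.tsv")
    for (p in c(paths, peaks = file.path(outdir, "peaks.bed"),
                tss = file.path(outdir, "tss.tsv"))) {
      manifest <- .manifest_add(manifest, basename(p), p)
    }
  }

  needs_matrix <- any(c("normalize", "qc", "fit", "sweep", "robustness",
                        "behaviors", "enrich") %in% stages)
  if (needs_matrix) {
    if (is.null(config$expression) || is.null(config$sample_sheet)) {
      stop("missing input: expression and sample_sheet paths are required")
    }
    sheet <- read_sample_sheet(config$sample_sheet)
    if (!is.null(config$excluded_timepoints)) {
      ex <- config$excluded_timepoints  # list of c(condition, timepoint_h)
      for (e in ex) {
        sheet <- sheet[!(sheet$condition == e[[1]] &
                           sheet$timepoint_h == as.integer(e[[2]])), ]
      }
    }
    raw <- read_expression(config$expression, sheet)
    s <- size_factors(raw)
    norm <- normalize_counts(raw, s)
    filt <- filter_low_expressed(norm, floor = config$floor)
    tm <- average_replicates(filt, sheet)
    tm_scaled <- max_scale(tm)
  }

  if ("normalize" %in% stages) {
    p1 <- file.path(outdir, "normalized.tsv")
    write_expression(filt, p1)
    p2 <- file.path(outdir, "timepoint_matrix.tsv")
    write_timepoint_matrix(tm_scaled, p2)
    write.table(data.frame(sample_id = names(s), size_factor = s),
                file.path(outdir, "size_factors.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- .manifest_add(manifest, "normalized", p1)
    manifest <- .manifest_add(manifest, "timepoint_matrix", p2)
  }

  if ("qc" %in% stages) {
    pca <- pca_scores(filt)
    report <- replicate_zscores(pca, sheet, n_pcs = config$n_pcs,
                                threshold = config$z_threshold)
    p <- file.path(outdir, "outlier_report.tsv")
    write.table(report$table, p, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- .manifest_add(manifest, "outlier_report", p)
    cm <- pairwise_timepoint_correlation(tm)
    hc <- hierarchical_cluster(cm)
    writeLines(hc$newick, file.path(outdir, "timepoint_dendrogram.nwk"))
    write.table(cm$r, file.path(outdir, "timepoint_correlation.tsv"),
                sep = "\t", quote = FALSE)
    manifest$flagged_outliers <- report$flagged
  }

  if (any(c("fit", "behaviors", "enrich") %in% stages)) {
    model <- nmf_fit(tm_scaled, M = config$M, theta = config$theta,
                     seed = config$seed)
    pW <- file.path(outdir, "W.tsv"); pH <- file.path(outdir, "H.tsv")
    write_expression(model$W, pW)
    write_expression(model$H, pH)
    jsonlite::write_json(
      list(config = model$config, iterations = model$iterations,
           converged = model$converged,
           frobenius_trace = model$frobenius_trace),
      file.path(outdir, "nmf_model.json"), auto_unbox = TRUE, digits = NA)
    manifest <- .manifest_add(manifest, "W", pW)
    manifest <- .manifest_add(manifest, "H", pH)
  }

  if ("sweep" %in% stages) {
    sel <- sweep_rank(tm_scaled, M_range = config$M_range,
                      seed = config$seed, theta = config$theta)
    p <- file.path(outdir, "rank_sweep.tsv")
    write.table(
      data.frame(M = sel$M_values[-length(sel$M_values)],
                 rmse_successive = sel$rmse_successive,
                 rmse_fit = sel$rmse_fit[-length(sel$M_values)]),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- .manifest_add(manifest, "rank_sweep", p)
    manifest$local_minima <- sel$local_minima
  }

  if ("robustness" %in% stages) {
    rb <- nmf_robustness(tm_scaled, M = config$M,
                         n_runs = config$robustness_runs,
                         seed = config$seed, theta = config$theta)
    p <- file.path(outdir, "robustness.tsv")
    write.table(
      data.frame(kind = c(rep("pairwise", length(rb$rmse_pairwise)),
                          rep("to_data", length(rb$rmse_to_data))),
                 rmse = c(rb$rmse_pairwise, rb$rmse_to_data)),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- .manifest_add(manifest, "robustness", p)
  }

  top_lists <- NULL
  if (any(c("behaviors", "enrich") %in% stages)) {
    assignment <- dominant_behavior(model)
    ordering <- order_behaviors(model)
    write_assignment(assignment, file.path(outdir, "assignments.tsv"))
    write.table(ordering, file.path(outdir, "behavior_order.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(sort_genes_for_display(assignment, ordering),
               file.path(outdir, "display_order.txt"))
    top_lists <- lapply(seq_len(config$M), function(m) {
      tg <- top_genes(model, m, n = config$top_n,
                      expr_floor = config$expr_floor_go,
                      gene_max = tm_scaled$per_gene_max)
      write.table(tg, file.path(outdir, sprintf("top_genes_behavior%02d.tsv", m)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      tg$gene_id
    })
    names(top_lists) <- paste0("behavior", seq_len(config$M))
  }

  if ("enrich" %in% stages) {
    if (is.null(config$peaks) || is.null(config$tss)) {
      stop("missing input: peaks and tss paths are required for enrich")
    }
    peaks <- read_peaks(config$peaks)
    tss <- read_tss_table(config$tss)
    background <- names(tm_scaled$per_gene_max)[
      tm_scaled$per_gene_max >= config$background_floor]
    sets <- top_lists
    if (!is.null(config$de_tables)) {
      for (nm in names(config$de_tables)) {
        de <- read.delim(config$de_tables[[nm]], stringsAsFactors = FALSE)
        sets[[nm]] <- filter_deg_table(de, alpha = config$alpha,
                                       lfc = config$lfc)
      }
    }
    rep_tab <- enrichment_report(sets, peaks, tss, background,
                                 proximal_bp = config$proximal,
                                 distal_bp = config$distal)
    p <- file.path(outdir, "enrichment.tsv")
    write.table(rep_tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- .manifest_add(manifest, "enrichment", p)
  }

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
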