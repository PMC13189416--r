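#' Describe one ground-truth temporal behavior
#'
#' Shapes follow the taxonomy observed in myeloid differentiation
#' time courses: pulses with an onset and an offset, late monotone rises,
#' early drops, sustained activation and damped oscillations. A behavior is
#' active only in the conditions named by `condition_mask`; its row in the
#' behavior matrix is zero in the other condition block.
#'
#' @param behavior_id integer id.
#' @param condition_mask subset of `c("GCSF", "IL3")`.
#' @param shape one of `"pulse"`, `"late_rise"`, `"early_drop"`,
#'   `"sustained"`, `"oscillating"`.
#' @param onset_h,offset_h pulse boundaries in hours (offset used by
#'   `"pulse"` only; must exceed onset).
#' @param amplitude peak value of the behavior row.
#' @return A `behavior_spec` list.
#' @export
behavior_spec <- function(behavior_id, condition_mask,
                          shape = c("pulse", "late_rise", "early_drop",
                                    "sustained", "oscillating"),
                          onset_h = 0, offset_h = NA, amplitude = 1) {
  shape <- match.arg(shape)
  condition_mask <- unique(as.character(condition_mask))
  if (length(condition_mask) == 0L ||
      !all(condition_mask %in% c("GCSF", "IL3"))) {
    stop("condition_mask must be a non-empty subset of {GCSF, IL3}")
  }
  if (shape == "pulse") {
    if (is.na(offset_h) || !(onset_h < offset_h)) {
      stop("pulse requires onset_h < offset_h")
    }
  }
  if (amplitude <= 0) stop("amplitude must be positive")
  structure(list(behavior_id = as.integer(behavior_id),
                 condition_mask = condition_mask, shape = shape,
                 onset_h = onset_h, offset_h = offset_h,
                 amplitude = amplitude),
            class = "behavior_spec")
}

# logistic rise centred at x0 with width (hours per e-fold) w
.sigmoid <- function(t, x0, w = 2) 1 / (1 + exp(-(t - x0) / w))

# evaluate one shape on a time grid; non-negative, max-normalized to 1.
# Values below 1e-8 of the maximum are clamped to exact zero: a transcript
# far outside its expression window yields no counts, and exact zeros keep
# silent genes out of the median-of-ratios reference set.
.shape_curve <- function(shape, t, onset, offset) {
  y <- switch(
    shape,
    pulse = .sigmoid(t, onset) * (1 - .sigmoid(t, offset)),
    late_rise = .sigmoid(t, onset, w = 8),
    early_drop = 1 - .sigmoid(t, onset, w = 4),
    # near-constant expression with a shallow early rise: the
    # housekeeping-like component real count data always contains
    sustained = 0.85 + 0.15 * .sigmoid(t, onset, w = 8),
    oscillating = .sigmoid(t, onset) *
      (0.55 + 0.45 * sin(2 * pi * (t - onset) / 48))
  )
  if (max(y) > 0) y <- y / max(y)
  y[y < 1e-8] <- 0
  y
}

#' Evaluate ground-truth behaviors on the experimental grid
#'
#' @param specs list of [behavior_spec()] objects.
#' @param grid named list with `GCSF` and `IL3` timepoint vectors (defaults
#'   to [build_timepoint_grid()] for each condition).
#' @return K x (T_G + T_I) matrix with condition/timepoint column labels
#'   (attributes `condition`, `timepoint_h`); row maxima equal the
#'   amplitudes.
#' @export
make_behaviors <- function(specs,
                           grid = list(GCSF = build_timepoint_grid("GCSF"),
                                       IL3 = build_timepoint_grid("IL3"))) {
  condition <- rep(c("GCSF", "IL3"), times = c(length(grid$GCSF), length(grid$IL3)))
  timepoint_h <- c(grid$GCSF, grid$IL3)
  H <- t(vapply(specs, function(sp) {
    row <- numeric(length(timepoint_h))
    for (cond in sp$condition_mask) {
      idx <- which(condition == cond)
      row[idx] <- .shape_curve(sp$shape, timepoint_h[idx],
                               sp$onset_h, sp$offset_h)
    }
    if (max(row) > 0) row <- row * sp$amplitude / max(row)
    row
  }, numeric(length(timepoint_h))))
  rownames(H) <- paste0("behavior", vapply(specs, `[[`, integer(1), "behavior_id"))
  colnames(H) <- paste0(condition, "_", timepoint_h, "h")
  attr(H, "condition") <- condition
  attr(H, "timepoint_h") <- timepoint_h
  H
}

#' The default five-behavior truth used by the bundled fixture
#'
#' A GCSF-specific early pulse, a GCSF late rise, a shared mid pulse
#' (active in both conditions), an IL3 early pulse, and a near-constant
#' sustained component shared by both conditions -- a reduced version of
#' the pulse/late-activation taxonomy of two-condition differentiation
#' data, plus the housekeeping-like fraction that anchors median-of-ratios
#' normalization in any real transcriptome.
#'
#' @return list of [behavior_spec()] objects.
#' @export
default_behavior_specs <- function() {
  list(
    behavior_spec(1L, "GCSF", "pulse", onset_h = 2, offset_h = 48),
    behavior_spec(2L, "GCSF", "late_rise", onset_h = 100),
    behavior_spec(3L, c("GCSF", "IL3"), "pulse", onset_h = 8, offset_h = 80),
    behavior_spec(4L, "IL3", "pulse", onset_h = 0, offset_h = 8),
    behavior_spec(5L, c("GCSF", "IL3"), "sustained", onset_h = 8)
  )
}

#' Sparse non-negative gene weights with one designated dominant behavior
#'
#' Each gene is assigned a designated behavior (cycled over `1:K`); its
#' dominant weight is drawn from a heavy-tailed positive law (lognormal).
#' Each off-dominant entry is zero with probability `sparsity`, otherwise a
#' fraction (< 1) of the dominant weight, so at `sparsity = 1` every row has
#' exactly one nonzero entry and the argmax equals the designated behavior.
#'
#' @param G,K gene and behavior counts.
#' @param sparsity probability in (0, 1] that an off-dominant weight is zero.
#' @param seed RNG seed.
#' @return G x K non-negative matrix with attribute `designated` (integer
#'   vector of true dominant behaviors).
#' @export
make_weights <- function(G, K, sparsity = 0.9, seed = 20240101) {
  if (sparsity < 0 || sparsity > 1) stop("sparsity must be in [0, 1]")
  set.seed(seed)
  designated <- rep_len(seq_len(K), G)
  W <- matrix(0, G, K)
  dom <- rlnorm(G, meanlog = 0, sdlog = 0.8)
  W[cbind(seq_len(G), designated)] <- dom
  off <- matrix(runif(G * K) >= sparsity, G, K)
  off[cbind(seq_len(G), designated)] <- FALSE
  n_off <- sum(off)
  if (n_off > 0) {
    W[off] <- (dom[row(off)[off]]) * runif(n_off, 0, 0.6)
  }
  rownames(W) <- sprintf("gene%04d", seq_len(G))
  colnames(W) <- paste0("behavior", seq_len(K))
  attr(W, "designated") <- designated
  W
}

#' Compose a per-replicate synthetic expression dataset
#'
#' Per-replicate values are `count_scale * (W H)_gt * exp(e)` with `e`
#' lognormal multiplicative noise of coefficient of variation `cv` and unit
#' mean, so the replicate mean converges to `count_scale * W H`. A sample
#' sheet on the experimental grid is built alongside.
#'
#' @param true_W G x K weights (from [make_weights()]).
#' @param true_H K x T behaviors (from [make_behaviors()]), with condition
#'   and timepoint attributes.
#' @param cv replicate coefficient of variation (0 = noise-free).
#' @param count_scale multiplier taking unit-scale behaviors to count scale.
#' @param replicates replicates per (condition, timepoint).
#' @param seed RNG seed.
#' @return `synthetic_dataset` list: `expression` (genes x samples),
#'   `sheet`, `true_W`, `true_H`, `noise_params`, `planted_outliers`, `seed`.
#' @export
compose_expression <- function(true_W, true_H, cv = 0.1, count_scale = 100,
                               replicates = 3, seed = 20240101) {
  condition <- attr(true_H, "condition")
  timepoint_h <- attr(true_H, "timepoint_h")
  stopifnot(!is.null(condition), ncol(true_W) == nrow(true_H))
  mean_expr <- count_scale * (true_W %*% true_H)
  set.seed(seed)
  sdlog <- sqrt(log(1 + cv^2))
  cols <- list(); sheet <- list()
  k <- 0L
  for (j in seq_along(condition)) {
    for (r in seq_len(replicates)) {
      k <- k + 1L
      noise <- if (cv > 0) {
        exp(rnorm(nrow(mean_expr), mean = -sdlog^2 / 2, sd = sdlog))
      } else rep(1, nrow(mean_expr))
      cols[[k]] <- mean_expr[, j] * noise
      sheet[[k]] <- data.frame(
        sample_id = sprintf("%s_%dh_r%d", condition[j], timepoint_h[j], r),
        condition = condition[j], timepoint_h = timepoint_h[j],
        replicate = r, stringsAsFactors = FALSE)
    }
  }
  expr <- do.call(cbind, cols)
  sheet <- do.call(rbind, sheet)
  colnames(expr) <- sheet$sample_id
  rownames(expr) <- rownames(true_W)
  structure(list(expression = expr, sheet = validate_sample_sheet(sheet),
                 true_W = true_W, true_H = true_H,
                 noise_params = list(cv = cv, count_scale = count_scale),
                 planted_outliers = list(), seed = seed),
            class = "synthetic_dataset")
}

#' The default synthetic fixture
#'
#' 2,000 genes, the five default behaviors, replicate CV 0.1, 3 replicates,
#' weight sparsity 0.9, seed 20240101.
#'
#' @param G,cv,replicates,sparsity,seed,count_scale see
#'   [compose_expression()] / [make_weights()].
#' @param specs behavior specs (default [default_behavior_specs()]).
#' @return `synthetic_dataset`.
#' @export
default_fixture <- function(G = 2000, cv = 0.1, replicates = 3,
                            sparsity = 0.9, seed = 20240101,
                            count_scale = 100,
                            specs = default_behavior_specs()) {
  H <- make_behaviors(specs)
  W <- make_weights(G, nrow(H), sparsity = sparsity, seed = seed)
  ds <- compose_expression(W, H, cv = cv, count_scale = count_scale,
                           replicates = replicates, seed = seed + 1L)
  ds
}

#' Plant an outlier replicate
#'
#' Multiplies a random 30% of the genes in one sample by `(1 + shift)` and
#' records the intervention.
#'
#' @param ds `synthetic_dataset`.
#' @param sample_id sample to perturb.
#' @param shift shift magnitude (0 leaves the data unchanged).
#' @param seed RNG seed for the gene subset.
#' @export
plant_outlier <- function(ds, sample_id, shift, seed = 1) {
  if (!sample_id %in% colnames(ds$expression)) {
    stop("unknown sample_id: ", sample_id)
  }
  if (shift != 0) {
    set.seed(seed)
    idx <- sample(nrow(ds$expression), size = round(0.3 * nrow(ds$expression)))
    ds$expression[idx, sample_id] <- ds$expression[idx, sample_id] * (1 + shift)
    ds$planted_outliers <- c(ds$planted_outliers,
                             list(list(sample_id = sample_id, shift = shift)))
  }
  ds
}

#' Toy peak set, TSS annotation and foreground gene set
#'
#' Places `G` genes on one synthetic chromosome with 120 kb spacing (so
#' +/-50 kb windows never touch), designates a foreground set, and drops a
#' proximal peak (200 bp, 200 bp downstream of the TSS) for each bound gene;
#' foreground and background genes are bound at the stated fractions.
#'
#' @param G gene count.
#' @param bound_fraction_fg,bound_fraction_bg binding rates in the
#'   foreground set and in the rest of the genes.
#' @param n_fg foreground size (default 5% of genes, at least 50 -- the
#'   scale of a differentially-expressed gene set relative to the expressed
#'   background, so the background binding rate stays close to
#'   `bound_fraction_bg`).
#' @param seed RNG seed.
#' @return list with `peaks` (`GRanges`), `tss` (data.frame: chrom, tss_pos,
#'   strand, gene_id, transcript_id, baseline_expr), `foreground` (gene ids).
#' @export
make_peaks_and_annotation <- function(G, bound_fraction_fg, bound_fraction_bg,
                                      n_fg = max(50L, G %/% 20L),
                                      seed = 20240101) {
  if (bound_fraction_fg < 0 || bound_fraction_fg > 1 ||
      bound_fraction_bg < 0 || bound_fraction_bg > 1) {
    stop("bound fractions must be in [0, 1]")
  }
  set.seed(seed)
  gene_id <- sprintf("gene%04d", seq_len(G))
  tss_pos <- 200000 + (seq_len(G) - 1L) * 120000
  tss <- data.frame(chrom = "chrS", tss_pos = tss_pos,
                    strand = sample(c("+", "-"), G, replace = TRUE),
                    gene_id = gene_id,
                    transcript_id = paste0(gene_id, ".t1"),
                    baseline_expr = rlnorm(G, 3, 1),
                    stringsAsFactors = FALSE)
  fg <- sample(gene_id, n_fg)
  is_fg <- gene_id %in% fg
  bound <- ifelse(is_fg, runif(G) < bound_fraction_fg,
                  runif(G) < bound_fraction_bg)
  start0 <- tss_pos[bound] + 200  # 0-based proximal peak
  peaks <- GenomicRanges::GRanges(
    seqnames = "chrS",
    ranges = IRanges::IRanges(start = start0 + 1L, end = start0 + 200L))
  list(peaks = peaks, tss = tss, foreground = sort(fg))
}

#' Write a synthetic dataset's fixture files
#'
#' Expression TSV, sample sheet CSV and a truth JSON (noise parameters,
#' planted outliers, designated behaviors and file pointers).
#'
#' @param ds `synthetic_dataset`.
#' @param dir output directory (created).
#' @return Named vector of file paths.
#' @export
write_synthetic_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             sheet = file.path(dir, "sample_sheet.csv"),
             true_W = file.path(dir, "true_W.tsv"),
             true_H = file.path(dir, "true_H.tsv"),
             truth = file.path(dir, "truth.json"))
  write_expression(ds$expression, paths[["expression"]])
  write.table(ds$sheet, paths[["sheet"]], sep = ",", quote = FALSE,
              row.names = FALSE)
  write_expression(ds$true_W, paths[["true_W"]])
  write_expression(ds$true_H, paths[["true_H"]])
  jsonlite::write_json(
    list(seed = ds$seed, noise_params = ds$noise_params,
         planted_outliers = ds$planted_outliers,
         designated = attr(ds$true_W, "designated"),
         files = as.list(basename(paths[-5L]))),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  paths
}

#' Write a peak set as BED (0-based half-open)
#' @param peaks `GRanges`.
#' @param path BED path.
#' @export
write_peaks_bed <- function(peaks, path) {
  rtracklayer::export(peaks, path, format = "BED")
  invisible(path)
}

#' Write a TSS annotation table as TSV
#' @param tss annotation data.frame.
#' @param path TSV path.
#' @export
write_tss_table <- function(tss, path) {
  write.table(tss, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
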