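#' Experimental timepoint grid for one condition
#'
#' The dense post-induction sampling schedule: every hour to 4 h, every 4 h
#' to 24 h, then every 8 h to the end of day 7 (168 h) -- 27 post-induction
#' timepoints per condition. The GCSF (neutrophil) arm additionally carries
#' the undifferentiated baseline at -48 h and the post-pre-treatment sample
#' at 0 h; the IL3 (macrophage) arm carries only its 0 h baseline.
#'
#' @param condition `"GCSF"` or `"IL3"`.
#' @param include_baseline prepend the pre-induction points (default `TRUE`).
#' @return Integer vector of timepoints in hours, strictly increasing.
#' @examples
#' length(build_timepoint_grid("GCSF", include_baseline = FALSE)) # 27
#' @export
build_timepoint_grid <- function(condition = c("GCSF", "IL3"),
                                 include_baseline = TRUE) {
  condition <- match.arg(condition)
  post <- c(1:4, seq(8L, 24L, by = 4L), seq(32L, 168L, by = 8L))
  if (!include_baseline) {
    return(post)
  }
  pre <- if (condition == "GCSF") c(-48L, 0L) else 0L
  c(pre, post)
}

#' Read and validate a sample sheet
#'
#' Columns: `sample_id`, `condition` (GCSF or IL3), `timepoint_h` (integer
#' hours; may be negative for pre-treatment), `replicate` (positive integer).
#' A sample id may appear under more than one (condition, timepoint) label:
#' the undifferentiated baseline is shared between the GCSF -48 h and IL3
#' 0 h labels and is listed once per label.
#'
#' @param path CSV or TSV file with a header (delimiter sniffed).
#' @return A validated `data.frame`.
#' @export
read_sample_sheet <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  sheet <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  validate_sample_sheet(sheet)
}

#' @rdname read_sample_sheet
#' @param sheet a data.frame to validate in place.
#' @export
validate_sample_sheet <- function(sheet) {
  need <- c("sample_id", "condition", "timepoint_h", "replicate")
  miss <- setdiff(need, names(sheet))
  if (length(miss) > 0) {
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  }
  sheet$sample_id <- as.character(sheet$sample_id)
  sheet$condition <- as.character(sheet$condition)
  sheet$timepoint_h <- as.integer(sheet$timepoint_h)
  sheet$replicate <- as.integer(sheet$replicate)
  if (!all(sheet$condition %in% c("GCSF", "IL3"))) {
    stop("condition must be GCSF or IL3")
  }
  if (any(sheet$replicate < 1L)) stop("replicate indices must be positive")
  key <- paste(sheet$sample_id, sheet$condition, sheet$timepoint_h)
  if (anyDuplicated(key)) {
    stop("duplicate sample sheet row: ", key[duplicated(key)][1L])
  }
  sheet
}

# Ordered (condition, timepoint) labels: GCSF block then IL3 block,
# time ascending within each block.
timepoint_labels <- function(sheet) {
  labs <- unique(sheet[, c("condition", "timepoint_h")])
  labs <- labs[order(match(labs$condition, c("GCSF", "IL3")), labs$timepoint_h), ]
  rownames(labs) <- NULL
  labs
}

#' Read an expression table aligned to a sample sheet
#'
#' Expects a tab-delimited file whose first column (`gene_id`) holds unique
#' gene/transcript ids and whose remaining columns are samples. Columns are
#' reordered to the sample sheet's (unique) sample order; every sheet sample
#' must be present.
#'
#' @param path TSV path.
#' @param sheet validated sample sheet.
#' @return Numeric matrix (genes x samples) with dimnames.
#' @export
read_expression <- function(path, sheet) {
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  gene_ids <- as.character(df[[1L]])
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene id: ", gene_ids[duplicated(gene_ids)][1L])
  }
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- gene_ids
  wanted <- unique(sheet$sample_id)
  miss <- setdiff(wanted, colnames(mat))
  if (length(miss) > 0) {
    stop("missing sample id in expression table: ", miss[1L])
  }
  mat <- mat[, wanted, drop = FALSE]
  check_expression(mat)
  mat
}

check_expression <- function(mat) {
  if (any(!is.finite(mat))) stop("non-finite expression value")
  if (any(mat < 0)) {
    bad <- which(mat < 0, arr.ind = TRUE)[1L, ]
    stop("negative value at gene ", rownames(mat)[bad[1L]],
         ", sample ", colnames(mat)[bad[2L]])
  }
  invisible(mat)
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over reference genes of
#' the ratio of that gene's abundance in the sample to the gene's geometric
#' mean across all samples. Reference genes are the rows with strictly
#' positive values in every sample. Size factors measure *relative* library
#' depth, so their overall scale is arbitrary; the returned factors are
#' fixed to geometric mean 1 (the same convention as edgeR's normalization
#' factors), which keeps normalized counts on the raw-count scale and makes
#' the size factors of an already-normalized table exactly 1.
#'
#' @param mat non-negative genes x samples matrix.
#' @return Named positive numeric vector, one entry per sample, geometric
#'   mean 1.
#' @export
size_factors <- function(mat) {
  check_expression(mat)
  ref <- rowSums(mat <= 0) == 0L
  if (!any(ref)) stop("no reference genes (no all-positive row)")
  lm <- log(mat[ref, , drop = FALSE])
  loggeo <- rowMeans(lm)
  s <- apply(exp(lm - loggeo), 2L, median)
  if (any(!is.finite(s)) || any(s <= 0)) stop("degenerate size factor")
  s / exp(mean(log(s)))
}

#' Divide each sample by its size factor
#'
#' @param mat genes x samples matrix.
#' @param s size factors as returned by [size_factors()].
#' @return Normalized matrix of the same shape.
#' @export
normalize_counts <- function(mat, s) {
  if (length(s) != ncol(mat)) stop("size factor length != sample count")
  sweep(mat, 2L, s, "/")
}

#' Drop low-expressed genes
#'
#' Removes genes whose normalized count is below `floor` in every sample,
#' i.e. keeps exactly the genes whose per-row maximum is >= `floor`.
#'
#' @param mat normalized genes x samples matrix.
#' @param floor expression floor (default 5).
#' @export
filter_low_expressed <- function(mat, floor = 5) {
  keep <- apply(mat, 1L, max) >= floor
  if (!any(keep)) stop("empty matrix: all genes below floor")
  mat[keep, , drop = FALSE]
}

#' Replicate-averaged condition-concatenated timepoint matrix
#'
#' Averages replicate samples into one column per (condition, timepoint) and
#' orders the columns as the GCSF block (time ascending) followed by the IL3
#' block. A sample listed in the sheet under two labels (the shared
#' undifferentiated baseline) contributes its values to both columns.
#'
#' @param mat normalized, filtered genes x samples matrix.
#' @param sheet validated sample sheet.
#' @return A `timepoint_matrix` object: list with `values` (genes x
#'   timepoints), `condition`, `timepoint_h` (per column), `scaled` flag and
#'   `per_gene_max` (filled by [max_scale()]).
#' @export
average_replicates <- function(mat, sheet) {
  sheet <- validate_sample_sheet(sheet)
  labs <- timepoint_labels(sheet)
  cols <- lapply(seq_len(nrow(labs)), function(i) {
    ids <- sheet$sample_id[sheet$condition == labs$condition[i] &
                             sheet$timepoint_h == labs$timepoint_h[i]]
    ids <- intersect(ids, colnames(mat))
    if (length(ids) == 0L) {
      stop("no replicates for ", labs$condition[i], " ", labs$timepoint_h[i], "h")
    }
    rowMeans(mat[, ids, drop = FALSE])
  })
  values <- do.call(cbind, cols)
  colnames(values) <- paste0(labs$condition, "_", labs$timepoint_h, "h")
  new_timepoint_matrix(values, labs$condition, labs$timepoint_h,
                       scaled = FALSE, per_gene_max = NULL)
}

new_timepoint_matrix <- function(values, condition, timepoint_h,
                                 scaled, per_gene_max) {
  stopifnot(ncol(values) == length(condition),
            length(condition) == length(timepoint_h))
  structure(
    list(values = values, condition = condition,
         timepoint_h = as.integer(timepoint_h),
         scaled = scaled, per_gene_max = per_gene_max),
    class = "timepoint_matrix"
  )
}

#' @export
print.timepoint_matrix <- function(x, ...) {
  cat(sprintf(
    "timepoint_matrix: %d genes x %d timepoints (GCSF %d + IL3 %d), %s\n",
    nrow(x$values), ncol(x$values), sum(x$condition == "GCSF"),
    sum(x$condition == "IL3"), if (x$scaled) "max-scaled" else "unscaled"))
  invisible(x)
}

#' Scale each gene to unit maximum
#'
#' Divides every row by its maximum over all timepoints and both condition
#' blocks jointly, so each expressed gene peaks at 1. All-zero rows are left
#' at zero. The pre-scaling per-gene maxima are recorded (they carry the
#' expression-floor information used downstream).
#'
#' @param tm unscaled `timepoint_matrix`.
#' @return Scaled `timepoint_matrix` with `per_gene_max` filled.
#' @export
max_scale <- function(tm) {
  stopifnot(inherits(tm, "timepoint_matrix"))
  if (isTRUE(tm$scaled)) stop("matrix already scaled")
  mx <- apply(tm$values, 1L, max)
  div <- ifelse(mx > 0, mx, 1)
  new_timepoint_matrix(tm$values / div, tm$condition, tm$timepoint_h,
                       scaled = TRUE, per_gene_max = setNames(mx, rownames(tm$values)))
}

#' Write / read a timepoint matrix as TSV with two header rows
#'
#' Row 1 holds the condition of each column, row 2 the timepoint in hours;
#' subsequent rows are `gene_id` followed by values.
#'
#' @param tm a `timepoint_matrix`.
#' @param path output TSV path.
#' @export
write_timepoint_matrix <- function(tm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("condition", tm$condition), collapse = "\t"), con)
  writeLines(paste(c("timepoint_h", tm$timepoint_h), collapse = "\t"), con)
  df <- data.frame(gene_id = rownames(tm$values), tm$values,
                   check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_timepoint_matrix
#' @param scaled whether the stored matrix was max-scaled.
#' @export
read_timepoint_matrix <- function(path, scaled = FALSE) {
  lines <- readLines(path)
  condition <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]][-1L]
  timepoint_h <- as.integer(strsplit(lines[2L], "\t", fixed = TRUE)[[1L]][-1L])
  body <- read.delim(text = lines[-(1:2)], header = FALSE,
                     stringsAsFactors = FALSE)
  values <- as.matrix(body[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- as.character(body[[1L]])
  colnames(values) <- paste0(condition, "_", timepoint_h, "h")
  per_gene_max <- if (scaled) NULL else NULL
  new_timepoint_matrix(values, condition, timepoint_h,
                       scaled = scaled, per_gene_max = per_gene_max)
}

#' Write an expression matrix as TSV
#' @param mat genes x samples matrix with dimnames.
#' @param path output path.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
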