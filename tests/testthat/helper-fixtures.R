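# Shared fixtures, built once per test run on first use.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# default study-condition fixture processed through the pipeline front end
fixture_default <- function() {
  cached("default", function() {
    ds <- default_fixture()
    s <- size_factors(ds$expression)
    filt <- filter_low_expressed(normalize_counts(ds$expression, s), 5)
    tm <- average_replicates(filt, ds$sheet)
    list(ds = ds, filt = filt, tm = tm, tm_scaled = max_scale(tm))
  })
}

# noise-free, fully sparse variant (exact rank-5 structure)
fixture_noise_free <- function() {
  cached("noise_free", function() {
    ds <- default_fixture(cv = 0, sparsity = 1, replicates = 1)
    s <- size_factors(ds$expression)
    filt <- filter_low_expressed(normalize_counts(ds$expression, s), 5)
    list(ds = ds, filt = filt,
         tm_scaled = max_scale(average_replicates(filt, ds$sheet)))
  })
}

# fraction of genes assigned their designated ground-truth behavior,
# after matching fitted to true behaviors by best correlation
recovery_fraction <- function(fit, ds) {
  m <- match_behaviors(fit$H, ds$true_H)
  asg <- dominant_behavior(fit)
  truth <- attr(ds$true_W, "designated")[match(asg$gene_id,
                                               rownames(ds$true_W))]
  mean(asg$dominant_behavior == m$perm[truth], na.rm = TRUE)
}

# independent scalar-arithmetic oracle for one multiplicative update:
# explicit index loops, no matrix algebra shared with the implementation
update_step_oracle <- function(X, W, H, eps = 1e-12) {
  G <- nrow(X); T_ <- ncol(X); M <- ncol(W)
  W1 <- matrix(0, G, M)
  for (g in seq_len(G)) for (m in seq_len(M)) {
    num <- 0; den <- 0
    for (t in seq_len(T_)) {
      num <- num + X[g, t] * H[m, t]
      wh <- 0
      for (mm in seq_len(M)) wh <- wh + W[g, mm] * H[mm, t]
      den <- den + wh * H[m, t]
    }
    W1[g, m] <- W[g, m] * num / (den + eps)
  }
  H1 <- matrix(0, M, T_)
  for (m in seq_len(M)) for (t in seq_len(T_)) {
    num <- 0; den <- 0
    for (g in seq_len(G)) {
      num <- num + W1[g, m] * X[g, t]
      wh <- 0
      for (mm in seq_len(M)) wh <- wh + W1[g, mm] * H[mm, t]
      den <- den + W1[g, m] * wh
    }
    H1[m, t] <- H[m, t] * num / (den + eps)
  }
  list(W = W1, H = H1)
}

# choose()-based upper-tail hypergeometric enumeration (independent of
# dhyper): P(X >= T_p) for X = bound genes among T_n drawn from A_n with
# A_p bound
fisher_enum_oracle <- function(T_p, T_n, A_p, A_n) {
  ks <- max(0, T_n - (A_n - A_p)):min(A_p, T_n)
  pmf <- choose(A_p, ks) * choose(A_n - A_p, T_n - ks) / choose(A_n, T_n)
  sum(pmf[ks >= T_p])
}

# brute-force window-binding oracle: all peaks x all genes, inclusive
# 0-based windows [tss - w, tss + w], distal excludes the proximal zone
assign_windows_oracle <- function(peak_df, tss, proximal_bp = 1000,
                                  distal_bp = 50000) {
  overlaps <- function(p_start, p_end, lo, hi) {
    # peak [p_start, p_end) 0-based vs inclusive [lo, hi], clipped at 0
    lo <- max(lo, 0)
    hi >= lo && p_start <= hi && p_end - 1 >= lo
  }
  bp <- logical(nrow(tss)); bd <- logical(nrow(tss))
  for (i in seq_len(nrow(tss))) {
    tp <- tss$tss_pos[i]
    for (j in seq_len(nrow(peak_df))) {
      if (peak_df$chrom[j] != tss$chrom[i]) next
      s <- peak_df$start[j]; e <- peak_df$end[j]
      if (overlaps(s, e, tp - proximal_bp, tp + proximal_bp)) bp[i] <- TRUE
      if (overlaps(s, e, tp - distal_bp, tp - proximal_bp - 1) ||
          overlaps(s, e, tp + proximal_bp + 1, tp + distal_bp)) bd[i] <- TRUE
    }
  }
  data.frame(gene_id = tss$gene_id, bound_proximal = bp, bound_distal = bd,
             stringsAsFactors = FALSE)
}

make_sheet <- function(conditions, timepoints, replicates) {
  do.call(rbind, lapply(seq_along(conditions), function(i) {
    data.frame(sample_id = sprintf("%s_%dh_r%d", conditions[i],
                                   timepoints[i], seq_len(replicates[i])),
               condition = conditions[i], timepoint_h = timepoints[i],
               replicate = seq_len(replicates[i]),
               stringsAsFactors = FALSE)
  }))
}
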