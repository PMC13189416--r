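#' Seeded uniform initialization of the NMF factors
#'
#' Entries of both factors are drawn iid from Uniform[0, 1).
#'
#' @param G,M,T_total matrix dimensions (genes, behaviors, timepoints).
#' @param seed RNG seed.
#' @return list with `W0` (G x M) and `H0` (M x T_total).
#' @export
nmf_init <- function(G, M, T_total, seed) {
  stopifnot(G >= 1, M >= 1, T_total >= 1)
  set.seed(seed)
  list(W0 = matrix(runif(G * M), G, M),
       H0 = matrix(runif(M * T_total), M, T_total))
}

#' Poisson-likelihood objective (diagnostic)
#'
#' `O(W, H) = sum_gt [ X_gt log((WH)_gt + eps) - (WH)_gt ]`. Reported as a
#' trace diagnostic alongside the Frobenius gap; the iteration and stopping
#' rule are Frobenius-based.
#'
#' @param X data matrix.
#' @param W,H current factors.
#' @param epsilon guard added inside the logarithm.
#' @export
nmf_objective <- function(X, W, H, epsilon = 1e-12) {
  WH <- W %*% H
  sum(X * log(WH + epsilon) - WH)
}

#' One multiplicative update of both factors
#'
#' The Frobenius (Euclidean) multiplicative updates, applied sequentially:
#' `W' = W o (X H^T) / (W H H^T + eps)` followed by
#' `H' = H o (W'^T X) / (W'^T W' H + eps)`, with `o` and the division
#' entrywise. Entries that are exactly zero stay zero.
#'
#' @param X non-negative data matrix (G x T).
#' @param W,H non-negative factors (G x M, M x T).
#' @param epsilon denominator guard.
#' @return list with updated `W` and `H`.
#' @export
nmf_update_step <- function(X, W, H, epsilon = 1e-12) {
  W <- W * (X %*% t(H)) / (W %*% tcrossprod(H) + epsilon)
  H <- H * (crossprod(W, X)) / (crossprod(W) %*% H + epsilon)
  list(W = W, H = H)
}

#' Frobenius norm of the reconstruction residual
#'
#' `F = ||X - W H||_F`.
#'
#' @inheritParams nmf_update_step
#' @export
frobenius_gap <- function(X, W, H) {
  sqrt(sum((X - W %*% H)^2))
}

#' Root-mean-square difference between two conformable matrices
#'
#' `rmse(A, B) = ||A - B||_F / sqrt(number of entries)`.
#'
#' @param A,B matrices of identical shape.
#' @export
rmse <- function(A, B) {
  if (!all(dim(A) == dim(B))) stop("shape mismatch")
  sqrt(sum((A - B)^2) / length(A))
}

#' Fit the NMF behavior model
#'
#' Alternates the multiplicative updates from a seeded uniform start until
#' the absolute change in the Frobenius residual between successive
#' iterations drops below `theta`, or `max_iter` is reached.
#'
#' @param X a max-scaled [timepoint_matrix] (each expressed gene peaking at
#'   1) or a plain non-negative matrix. An unscaled timepoint matrix is
#'   accepted only with `allow_unscaled = TRUE`.
#' @param M number of behaviors (default 10).
#' @param theta stopping threshold on `|F_k - F_{k-1}|` (default 0.05).
#' @param max_iter iteration safeguard (default 10000).
#' @param seed RNG seed for the uniform initialization.
#' @param epsilon denominator guard (default 1e-12).
#' @param W0,H0 optional explicit starting factors (override the seed).
#' @param allow_unscaled accept an unscaled timepoint matrix.
#' @return `nmf_model`: list with `W`, `H`, `frobenius_trace` (F at
#'   initialization and after each iteration), `objective_trace`,
#'   `iterations`, `converged`, `config`, and the column `condition` /
#'   `timepoint_h` labels when `X` was a timepoint matrix.
#' @export
nmf_fit <- function(X, M = 10, theta = 0.05, max_iter = 10000, seed = 1,
                    epsilon = 1e-12, W0 = NULL, H0 = NULL,
                    allow_unscaled = FALSE) {
  condition <- NULL; timepoint_h <- NULL
  if (inherits(X, "timepoint_matrix")) {
    if (!isTRUE(X$scaled) && !allow_unscaled) {
      stop("timepoint matrix is not max-scaled; pass allow_unscaled = TRUE to override")
    }
    condition <- X$condition; timepoint_h <- X$timepoint_h
    X <- X$values
  }
  stopifnot(is.matrix(X), all(X >= 0), theta > 0, M >= 1)
  if (is.null(W0) || is.null(H0)) {
    ini <- nmf_init(nrow(X), M, ncol(X), seed)
    if (is.null(W0)) W0 <- ini$W0
    if (is.null(H0)) H0 <- ini$H0
  }
  W <- W0; H <- H0
  f_trace <- frobenius_gap(X, W, H)
  o_trace <- nmf_objective(X, W, H, epsilon)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    up <- nmf_update_step(X, W, H, epsilon)
    W <- up$W; H <- up$H
    if (any(!is.finite(W)) || any(!is.finite(H))) {
      stop("non-finite factor entries at iteration ", iter)
    }
    f <- frobenius_gap(X, W, H)
    f_trace <- c(f_trace, f)
    o_trace <- c(o_trace, nmf_objective(X, W, H, epsilon))
    if (abs(f - f_trace[iter]) < theta) {
      converged <- TRUE
      break
    }
  }
  rownames(W) <- rownames(X)
  colnames(W) <- rownames(H) <- paste0("behavior", seq_len(M))
  colnames(H) <- colnames(X)
  structure(list(W = W, H = H, frobenius_trace = f_trace,
                 objective_trace = o_trace, iterations = iter,
                 converged = converged,
                 condition = condition, timepoint_h = timepoint_h,
                 config = list(M = M, theta = theta, max_iter = max_iter,
                               seed = seed, epsilon = epsilon)),
            class = "nmf_model")
}

#' @export
print.nmf_model <- function(x, ...) {
  cat(sprintf(
    "nmf_model: %d genes x %d behaviors x %d timepoints; %d iterations (%s); final F = %.4g\n",
    nrow(x$W), ncol(x$W), ncol(x$H), x$iterations,
    if (x$converged) "converged" else "max_iter reached",
    x$frobenius_trace[length(x$frobenius_trace)]))
  invisible(x)
}

#' Reconstruction of the model
#' @param model `nmf_model`.
#' @return `W %*% H`.
#' @export
nmf_approximation <- function(model) model$W %*% model$H

#' Rank selection sweep over the number of behaviors
#'
#' Fits the model at each rank in `M_range` (each with its own
#' deterministically derived seed, `seed + M`) and records the RMSE between
#' the reconstructions at successive ranks and between each reconstruction
#' and the data. The successive-approximation RMSE for rank M is
#' `rmse(approx_{M+1}, approx_M)` -- how much the reconstruction still
#' changes when one more behavior is allowed beyond M -- so its interior
#' local minimum marks the rank at which the patterns have been learned:
#' below it each added behavior captures real structure (large changes),
#' above it added behaviors chase noise (slowly growing run-to-run
#' differences). Plateaus are reported separately from strict minima.
#'
#' @param X scaled timepoint matrix or plain matrix.
#' @param M_range increasing integer ranks (length >= 3).
#' @param seed base seed; the fit at rank M uses `seed + M`.
#' @param ... further arguments to [nmf_fit()] (`theta`, `max_iter`, ...).
#' @return `model_selection`: list with `M_values`, `rmse_successive`
#'   (named by the smaller rank of each pair), `rmse_fit`, `local_minima`,
#'   `plateaus`, `converged` per rank.
#' @export
sweep_rank <- function(X, M_range = 2:15, seed = 1, ...) {
  M_range <- as.integer(M_range)
  if (length(M_range) < 3L || any(diff(M_range) <= 0)) {
    stop("M_range must be increasing with at least 3 values")
  }
  Xv <- if (inherits(X, "timepoint_matrix")) X$values else X
  approx <- vector("list", length(M_range))
  rmse_fit <- numeric(length(M_range))
  converged <- logical(length(M_range))
  for (i in seq_along(M_range)) {
    fit <- nmf_fit(X, M = M_range[i], seed = seed + M_range[i], ...)
    approx[[i]] <- nmf_approximation(fit)
    rmse_fit[i] <- rmse(approx[[i]], Xv)
    converged[i] <- fit$converged
  }
  rs <- vapply(seq_along(M_range)[-1L], function(i) {
    rmse(approx[[i]], approx[[i - 1L]])
  }, numeric(1))
  names(rs) <- M_range[-length(M_range)]
  interior <- seq_along(rs)[-c(1L, length(rs))]
  labels <- M_range[-length(M_range)]
  local_minima <- labels[interior[
    vapply(interior, function(i) rs[i] < rs[i - 1L] && rs[i] < rs[i + 1L],
           logical(1))]]
  plateaus <- labels[interior[
    vapply(interior,
           function(i) rs[i] <= rs[i - 1L] && rs[i] <= rs[i + 1L] &&
             (rs[i] == rs[i - 1L] || rs[i] == rs[i + 1L]),
           logical(1))]]
  structure(list(M_values = M_range, rmse_successive = rs,
                 rmse_fit = setNames(rmse_fit, M_range),
                 local_minima = local_minima, plateaus = plateaus,
                 converged = setNames(converged, M_range)),
            class = "model_selection")
}

#' Robustness of the factorization to random restarts
#'
#' Repeats the fit `n_runs` times from different seeded initializations and
#' compares every pairwise RMSE between reconstructions with each
#' reconstruction's RMSE to the data. Solutions are robust when the former
#' stay below the latter.
#'
#' @param X scaled timepoint matrix or plain matrix.
#' @param M rank.
#' @param n_runs number of restarts (default 100).
#' @param seed base seed; run r uses `seed + r`.
#' @param ... further arguments to [nmf_fit()].
#' @return `robustness_result`: list with `rmse_pairwise`
#'   (`n_runs (n_runs - 1) / 2` values) and `rmse_to_data` (`n_runs`
#'   values).
#' @export
nmf_robustness <- function(X, M = 10, n_runs = 100, seed = 1, ...) {
  Xv <- if (inherits(X, "timepoint_matrix")) X$values else X
  approx <- vector("list", n_runs)
  rmse_to_data <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    fit <- nmf_fit(X, M = M, seed = seed + r, ...)
    approx[[r]] <- nmf_approximation(fit)
    rmse_to_data[r] <- rmse(approx[[r]], Xv)
  }
  pairs <- utils::combn(n_runs, 2L)
  rmse_pairwise <- vapply(seq_len(ncol(pairs)), function(j) {
    rmse(approx[[pairs[1L, j]]], approx[[pairs[2L, j]]])
  }, numeric(1))
  structure(list(n_runs = n_runs, rmse_pairwise = rmse_pairwise,
                 rmse_to_data = rmse_to_data),
            class = "robustness_result")
}

#' Cumulative reconstruction of one gene from ordered behaviors
#'
#' Curve k is the partial sum over the first k behaviors (in the supplied
#' display order) of `W_gm H_m(t)`; the last curve is the model's full
#' reconstruction of the gene.
#'
#' @param model `nmf_model`.
#' @param gene gene id (row of `W`).
#' @param behavior_order permutation of behavior indices (default identity).
#' @return M x T matrix of cumulative curves.
#' @export
reconstruct_gene <- function(model, gene,
                             behavior_order = seq_len(ncol(model$W))) {
  if (!gene %in% rownames(model$W)) stop("unknown gene: ", gene)
  stopifnot(length(behavior_order) == ncol(model$W),
            all(sort(behavior_order) == seq_len(ncol(model$W))))
  contrib <- model$W[gene, behavior_order] * model$H[behavior_order, , drop = FALSE]
  curves <- apply(contrib, 2L, cumsum)
  if (is.null(dim(curves))) curves <- matrix(curves, nrow = 1L)
  rownames(curves) <- paste0("cum_", seq_len(nrow(curves)))
  colnames(curves) <- colnames(model$H)
  curves
}

#' Match fitted behaviors to reference behaviors by correlation
#'
#' NMF is identified only up to permutation and positive rescaling of the
#' behaviors, so comparisons against ground truth must first match fitted to
#' reference rows. For K <= 8 the assignment maximizing the total Pearson
#' correlation is found exactly over all permutations; larger K falls back
#' to greedy matching.
#'
#' @param H_fit,H_ref behavior matrices with equal column counts (rows =
#'   behaviors).
#' @return list with `perm` (index into `H_fit` rows for each `H_ref` row)
#'   and `cor` (matched correlations).
#' @export
match_behaviors <- function(H_fit, H_ref) {
  K <- nrow(H_ref)
  stopifnot(nrow(H_fit) == K, ncol(H_fit) == ncol(H_ref))
  cc <- suppressWarnings(cor(t(H_ref), t(H_fit)))
  cc[!is.finite(cc)] <- -1
  if (K <= 8L) {
    perms <- permutations_of(K)
    scores <- vapply(perms, function(p) sum(cc[cbind(seq_len(K), p)]),
                     numeric(1))
    best <- perms[[which.max(scores)]]
  } else {
    best <- integer(K)
    avail <- seq_len(K)
    for (i in order(apply(cc, 1L, max), decreasing = TRUE)) {
      j <- avail[which.max(cc[i, avail])]
      best[i] <- j
      avail <- setdiff(avail, j)
    }
  }
  list(perm = best, cor = cc[cbind(seq_len(K), best)])
}

permutations_of <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- permutations_of(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in 0:(n - 1L)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos)
    }
  }
  out
}
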