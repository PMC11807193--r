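# Missing-value imputation for single-cell copy-number matrices.
#
# Low-coverage scWGS leaves copy-number bins missing at random. Each
# missing value is filled with a distance-weighted average of the values
# that the most similar cells carry at the same bin: for cell i and bin j,
#
#   Xhat_ij = sum_k w_ik * X_kj / sum_k w_ik,   w_ik = 1 / d(i, k)
#
# over the k nearest neighbours of i that have an observed value at j.
# Distances are Euclidean over the bins observed in both cells, rescaled
# by sqrt(n_bins / n_jointly_observed) so that sparsity does not shrink
# them; a zero-distance neighbour's value is used directly.

#' Missing-aware cell-to-cell distance matrix
#'
#' Euclidean distances computed over pairwise-complete bins and rescaled by
#' `sqrt(n_bins / n_shared)`. Pairs with no shared observed bin get `Inf`.
#'
#' @param m copy-number matrix (cells x bins) with `NA` for missing.
#' @return symmetric cells x cells distance matrix with a zero diagonal.
#' @export
cn_distances <- function(m) {
  W <- !is.na(m)
  X <- m; X[!W] <- 0
  storage.mode(W) <- "double"
  G <- tcrossprod(X)             # sum of x_i x_k over shared bins
  S <- tcrossprod(X^2, W)        # sum of x_i^2 over shared bins
  C <- tcrossprod(W)             # number of shared bins
  D2 <- S + t(S) - 2 * G
  D2[D2 < 0] <- 0                # numerical noise
  D <- sqrt(D2 * ncol(m) / C)    # C = 0 yields Inf via division
  D[C == 0] <- Inf
  diag(D) <- 0
  dimnames(D) <- list(rownames(m), rownames(m))
  D
}

#' Distance-weighted k-nearest-neighbour imputation
#'
#' Fills every missing entry that has at least one observed value in its
#' bin. Observed entries are returned bit-identical; imputed values are
#' weighted means of neighbour values and are therefore not re-rounded.
#'
#' @param m copy-number matrix with `NA` for missing values.
#' @param k number of neighbours (default 5). If fewer eligible neighbours
#'   exist for some entries, all available ones are used (with a warning).
#' @return object of class `imputation_result`: `matrix` (completed),
#'   `imputed` (data.frame `row`, `col` of filled positions), `skipped`
#'   (positions left missing because their bin had no data), and `k`.
#' @export
knn_impute <- function(m, k = 5) {
  validate_cn_matrix(m)
  if (nrow(m) < k + 1) {
    warning("fewer than k + 1 = ", k + 1, " cells; using all available neighbours")
  }
  miss <- which(is.na(m), arr.ind = TRUE)
  if (nrow(miss) == 0) {
    return(structure(list(matrix = m,
                          imputed = data.frame(row = integer(0), col = integer(0)),
                          skipped = data.frame(row = integer(0), col = integer(0)),
                          k = k),
                     class = "imputation_result"))
  }
  D <- cn_distances(m)
  res <- .knn_impute_fill(m, D, as.integer(k))
  filled <- res$matrix
  dimnames(filled) <- dimnames(m)
  if (res$n_short > 0) {
    warning(res$n_short, " imputation(s) used fewer than k = ", k, " neighbours")
  }
  still <- is.na(filled[miss])
  structure(list(matrix = filled,
                 imputed = data.frame(row = miss[!still, 1], col = miss[!still, 2]),
                 skipped = data.frame(row = miss[still, 1], col = miss[still, 2]),
                 k = k),
            class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("KNN imputation (k = %d): %d values imputed, %d skipped (empty bins)\n",
              x$k, nrow(x$imputed), nrow(x$skipped)))
  invisible(x)
}

#' Baseline imputation methods
#'
#' Comparison baselines: `"median"` substitutes the per-bin median of the
#' observed values; `"random"` substitutes a value drawn uniformly from all
#' observed values of the matrix.
#'
#' @param m copy-number matrix with `NA` for missing values.
#' @param method `"median"` or `"random"`.
#' @param seed optional integer seed (random method).
#' @return an `imputation_result` (see [knn_impute()]).
#' @export
baseline_impute <- function(m, method = c("median", "random"), seed = NULL) {
  method <- match.arg(method)
  validate_cn_matrix(m)
  if (!is.null(seed)) withr::local_seed(seed)
  miss <- which(is.na(m), arr.ind = TRUE)
  filled <- m
  if (method == "median") {
    med <- apply(m, 2, stats::median, na.rm = TRUE)
    filled[miss] <- med[miss[, 2]]
  } else {
    pool <- m[!is.na(m)]
    if (length(pool) == 0) stop("no observed values to draw from")
    filled[miss] <- sample(pool, nrow(miss), replace = TRUE)
  }
  still <- is.na(filled[miss])
  structure(list(matrix = filled,
                 imputed = data.frame(row = miss[!still, 1], col = miss[!still, 2]),
                 skipped = data.frame(row = miss[still, 1], col = miss[still, 2]),
                 k = NA_integer_, method = method),
            class = "imputation_result")
}

#' Score an imputation against the unmasked original
#'
#' * accuracy: percentage of imputed values identical to the original;
#' * similarity: percentage of imputed values within +/-1 copy;
#' * invariance: percentage of all matrix values unchanged.
#'
#' @param original complete matrix before masking.
#' @param mask mask positions (`row`/`col` data.frame from [mask_random()]).
#' @param imputed completed matrix (or an `imputation_result`).
#' @return data.frame with columns `accuracy`, `similarity`, `invariance`
#'   (percentages).
#' @export
evaluate_imputation <- function(original, mask, imputed) {
  if (inherits(imputed, "imputation_result")) imputed <- imputed$matrix
  if (!all(dim(original) == dim(imputed))) stop("matrix shape mismatch")
  idx <- cbind(mask$row, mask$col)
  diff <- abs(imputed[idx] - original[idx])
  eq <- !is.na(diff) & diff < 1e-9
  close <- !is.na(diff) & diff <= 1 + 1e-9
  accuracy <- 100 * mean(eq)
  similarity <- 100 * mean(close)
  changed <- sum(!eq)  # only masked positions can differ
  invariance <- 100 * (length(original) - changed) / length(original)
  data.frame(accuracy = accuracy, similarity = similarity, invariance = invariance)
}

#' Masking benchmark across missing-data fractions
#'
#' Masks a complete matrix at each requested fraction, imputes with KNN and
#' the two baselines, and scores each against the original.
#'
#' @param m complete copy-number matrix.
#' @param fractions masking fractions to test.
#' @param k neighbours for [knn_impute()].
#' @param methods subset of `c("knn", "median", "random")`.
#' @param seed optional integer seed (controls masks and the random
#'   baseline).
#' @return data.frame: `fraction`, `method`, `accuracy`, `similarity`,
#'   `invariance`.
#' @export
impute_benchmark <- function(m, fractions = seq(0.05, 0.55, by = 0.05), k = 5,
                             methods = c("knn", "median", "random"),
                             seed = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (!is.null(seed)) withr::local_seed(seed)
  rows <- list()
  for (f in fractions) {
    masked <- mask_random(m, f)
    for (meth in methods) {
      res <- switch(meth,
                    knn = knn_impute(masked$matrix, k = k),
                    median = baseline_impute(masked$matrix, "median"),
                    random = baseline_impute(masked$matrix, "random"))
      rows[[length(rows) + 1]] <-
        data.frame(fraction = f, method = meth,
                   evaluate_imputation(m, masked$mask, res))
    }
  }
  do.call(rbind, rows)
}
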