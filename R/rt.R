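# Replication-timing comparison utilities.
#
# S-phase cells are binarised bin-by-bin into replicated/unreplicated by
# comparing their copy number with a non-replicating baseline profile;
# aggregating the binary calls per bin across cells gives a pseudo-bulk RT
# profile in [0, 1] (1 = earliest replicating). Profiles are compared with
# Spearman correlations ordered by Ward.D2 hierarchical clustering, and
# trajectory embeddings with a label-permutation test.

#' Binarise S-phase copy numbers into replication calls
#'
#' A bin counts as replicated when the cell's copy number reaches 1.5x the
#' non-replicating baseline for that bin (the midpoint between an
#' unreplicated 1x and a fully replicated 2x signal). This is a simplified
#' stand-in for per-cell threshold optimisation performed by dedicated scRT
#' callers; the threshold is recorded in the result.
#'
#' @param s_matrix copy-number matrix of S-phase cells.
#' @param baseline per-bin non-replicating baseline (e.g. the G1 median
#'   profile of the cell's subpopulation), aligned with `s_matrix` columns.
#' @param threshold replicated/unreplicated ratio cut (default 1.5).
#' @return object of class `binary_rt`: `matrix` (cells x bins, 0/1/NA)
#'   and per-cell `progress` (fraction of informative bins replicated).
#' @export
binarize_s_cells <- function(s_matrix, baseline, threshold = 1.5) {
  validate_cn_matrix(s_matrix)
  if (length(baseline) != ncol(s_matrix)) {
    stop("baseline must have one value per bin")
  }
  informative <- !is.na(s_matrix)
  bad <- which(colSums(informative) > 0 & (is.na(baseline) | baseline <= 0))
  if (length(bad)) {
    stop("baseline is zero or missing on bin(s) with S-phase data, e.g. ",
         colnames(s_matrix)[bad[1]])
  }
  ratio <- sweep(s_matrix, 2, baseline, "/")
  bin <- ifelse(ratio >= threshold, 1, 0)
  dimnames(bin) <- dimnames(s_matrix)
  progress <- rowMeans(bin, na.rm = TRUE)
  structure(list(matrix = bin, progress = progress, threshold = threshold),
            class = "binary_rt")
}

#' Pseudo-bulk replication-timing profile
#'
#' Per bin, the fraction of informative S cells in which the bin is
#' replicated. Bins with no informative cell are absent (NA).
#'
#' @param binary a `binary_rt` object or a cells x bins 0/1/NA matrix.
#' @return named numeric vector of per-bin RT values in \[0, 1\]
#'   (1 = earliest).
#' @export
pseudobulk_rt <- function(binary) {
  m <- if (inherits(binary, "binary_rt")) binary$matrix else binary
  if (nrow(m) < 1) stop("need at least one S cell")
  rt <- colMeans(m, na.rm = TRUE)
  rt[colSums(!is.na(m)) == 0] <- NA_real_
  rt
}

#' Spearman correlation atlas of RT profiles
#'
#' Pairwise Spearman correlations on the bins defined in both profiles,
#' with leaves ordered by Ward.D2 hierarchical clustering on
#' `1 - correlation`.
#'
#' @param profiles named list of per-bin RT vectors (shared naming), or a
#'   bins x profiles matrix.
#' @param min_shared minimum number of bins shared by a pair.
#' @return list with `correlation` (symmetric matrix, unit diagonal),
#'   `order` (dendrogram leaf order) and `hclust`.
#' @export
correlate_profiles <- function(profiles, min_shared = 3) {
  if (is.list(profiles)) {
    bins <- unique(unlist(lapply(profiles, names)))
    mat <- vapply(profiles, function(p) p[bins], numeric(length(bins)))
    rownames(mat) <- bins
  } else {
    mat <- as.matrix(profiles)
  }
  if (ncol(mat) < 2) stop("need at least two profiles")
  shared <- crossprod(!is.na(mat))
  if (any(shared < min_shared)) {
    stop("profile pair(s) share fewer than ", min_shared, " bins")
  }
  cors <- stats::cor(mat, method = "spearman", use = "pairwise.complete.obs")
  diag(cors) <- 1
  hc <- stats::hclust(stats::as.dist(1 - cors), method = "ward.D2")
  list(correlation = cors, order = hc$order, hclust = hc)
}

#' Permutation test for group separation in a trajectory embedding
#'
#' The observed statistic is the per-group absolute difference between the
#' mean first coordinate and the mean second coordinate, summed over
#' groups. Group labels are then shuffled `n_perm` times with coordinates
#' fixed, and the p-value is `(number of permuted statistics >= observed
#' + 1) / (n_perm + 1)`.
#'
#' The cross-axis form of the statistic is kept as published for the
#' default; `statistic = "centroid"` offers a conventional alternative
#' (sum of pairwise between-group centroid distances).
#'
#' @param coords 2-column coordinate matrix (one row per cell).
#' @param groups per-cell group labels; at least 2 groups of >= 2 cells.
#' @param n_perm number of permutations.
#' @param statistic `"cross_axis"` (default) or `"centroid"`.
#' @param seed optional integer seed.
#' @return list with `observed`, `p_value`, `n_perm`, `statistic`.
#' @export
trajectory_permutation_test <- function(coords, groups, n_perm = 1000,
                                        statistic = c("cross_axis", "centroid"),
                                        seed = NULL) {
  statistic <- match.arg(statistic)
  coords <- as.matrix(coords)
  if (ncol(coords) != 2) stop("coords must have exactly two columns")
  groups <- as.character(groups)
  if (length(groups) != nrow(coords)) stop("one group label per point required")
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least two groups")
  if (any(sizes < 2)) stop("every group needs at least 2 points")
  if (n_perm < 1) stop("'n_perm' must be >= 1")
  if (!is.null(seed)) withr::local_seed(seed)
  stat_fun <- if (statistic == "cross_axis") {
    function(g) {
      mx <- tapply(coords[, 1], g, mean)
      my <- tapply(coords[, 2], g, mean)
      sum(abs(mx - my))
    }
  } else {
    function(g) {
      cent <- cbind(tapply(coords[, 1], g, mean), tapply(coords[, 2], g, mean))
      sum(stats::dist(cent))
    }
  }
  observed <- stat_fun(groups)
  perm <- vapply(seq_len(n_perm), function(i) stat_fun(sample(groups)), 0)
  p <- (sum(perm >= observed) + 1) / (n_perm + 1)
  list(observed = observed, p_value = p, n_perm = n_perm,
       statistic = statistic)
}

#' Write pseudo-bulk RT profiles as bedGraph
#'
#' @param rt named per-bin RT vector ("chr:start-end" names).
#' @param path output file.
#' @param name track name recorded in the header line.
#' @return `path`, invisibly.
#' @export
write_rt_bedgraph <- function(rt, path, name = "pseudo_bulk_RT") {
  bins <- parse_regions(names(rt))
  keep <- !is.na(rt)
  out <- data.frame(bins[keep, c("chrom", "start", "end")], value = rt[keep])
  header <- sprintf("track type=bedGraph name=\"%s\"", name)
  writeLines(header, path)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, append = TRUE)
  invisible(path)
}
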