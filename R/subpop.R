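# Genomic subpopulation discovery.
#
# Non-replicating cells are embedded to two dimensions with UMAP and
# clustered with DBSCAN, whose neighbourhood radius is derived from the
# embedding's coordinate ranges and clamped to [1.25, 2]. Because UMAP is
# stochastic, the embedding/clustering step is repeated with six auxiliary
# seeds and the modal cluster count wins. Near-identical clusters (median
# profiles >= 98.5% identical) are merged. Replicating cells are then
# matched to the discovered groups by majority vote of their nearest
# non-replicating neighbours in a 10-dimensional embedding. Five artificial
# "calibration" cells with constant copy number 1-5 anchor the ploidy scale
# in both embeddings and are removed from all results.

DEFAULT_SEED <- 18671107L

# Constant-ploidy calibration profiles over the given regions.
calibration_profiles <- function(regions) {
  m <- matrix(rep(1:5, each = length(regions)), nrow = 5, byrow = TRUE)
  dimnames(m) <- list(paste0(".calibration_", 1:5), regions)
  m
}

# Seeded UMAP embedding; deterministic for a fixed seed (single-threaded).
umap_embed <- function(x, n_components, seed, n_neighbors = 15) {
  uwot::umap(x, n_components = n_components,
             n_neighbors = min(n_neighbors, nrow(x) - 1),
             n_threads = 1, n_sgd_threads = 0, seed = seed, verbose = FALSE)
}

#' DBSCAN neighbourhood radius from a 2-D embedding
#'
#' The radius is the ratio of the first coordinate's range to the second
#' coordinate's range, scaled by 1.25 and clamped to \[1.25, 2\]. The
#' `literal` flag reproduces the alternative reading in which the
#' denominator mixes axes (`max(coord2) - min(coord1)`).
#'
#' @param coords 2-column coordinate matrix.
#' @param lower,upper clamp bounds.
#' @param scale multiplier applied to the range ratio.
#' @param literal use the axis-mixing denominator variant.
#' @return epsilon value within `[lower, upper]`.
#' @export
epsilon_from_embedding <- function(coords, lower = 1.25, upper = 2,
                                   scale = 1.25, literal = FALSE) {
  if (nrow(coords) < 2) stop("need at least 2 points")
  r1 <- max(coords[, 1]) - min(coords[, 1])
  denom <- if (literal) max(coords[, 2]) - min(coords[, 1])
           else max(coords[, 2]) - min(coords[, 2])
  if (denom == 0) stop("zero range on the denominator coordinate")
  min(max(r1 / denom * scale, lower), upper)
}

#' Density-based clustering (DBSCAN)
#'
#' Classic DBSCAN on Euclidean distances: points with at least
#' `min_samples` neighbours within `eps` (the point itself included) are
#' core points; clusters grow from density-connected cores; remaining
#' points are noise (label 0).
#'
#' @param coords coordinate matrix (points x dimensions).
#' @param eps neighbourhood radius.
#' @param min_samples minimum neighbourhood size for a core point.
#' @return integer cluster labels (1..K, 0 = noise).
#' @export
dbscan_cluster <- function(coords, eps, min_samples) {
  n <- nrow(coords)
  D <- as.matrix(stats::dist(coords))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nb, length, 1L) >= min_samples
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    frontier <- nb[[i]]
    while (length(frontier)) {
      nxt <- integer(0)
      for (q in frontier) {
        if (labels[q] == 0L) {
          labels[q] <- cl
          if (core[q]) nxt <- c(nxt, nb[[q]])
        }
      }
      frontier <- unique(nxt)
    }
  }
  labels
}

# Attach DBSCAN noise points to the nearest cluster centroid.
attach_noise <- function(labels, coords) {
  noise <- which(labels == 0L)
  if (length(noise) == 0 || all(labels == 0L)) return(labels)
  cls <- sort(unique(labels[labels > 0L]))
  cent <- t(vapply(cls, function(k) colMeans(coords[labels == k, , drop = FALSE]),
                   numeric(ncol(coords))))
  for (i in noise) {
    d2 <- rowSums(sweep(cent, 2, coords[i, ], "-")^2)
    labels[i] <- cls[which.min(d2)]
  }
  labels
}

# Per-cluster median profiles (clusters x bins).
cluster_medians <- function(x, labels) {
  cls <- sort(unique(labels))
  med <- t(vapply(cls, function(k) {
    apply(x[labels == k, , drop = FALSE], 2, stats::median)
  }, numeric(ncol(x))))
  rownames(med) <- cls
  med
}

#' Merge near-identical subpopulations
#'
#' Pairwise identity between two clusters is the fraction of bins at which
#' their rounded median copy numbers agree. Pairs at or above `threshold`
#' are merged iteratively in descending-identity order, medians being
#' recomputed after every merge, until no pair qualifies. Labels are
#' renumbered 1..K by decreasing size.
#'
#' @param labels integer cluster labels (one per cell).
#' @param x feature matrix the medians are computed from (cells x bins).
#' @param threshold identity fraction at or above which clusters merge.
#' @param tolerance_identity alternative identity rule: bins agree when the
#'   absolute difference of the (unrounded) medians is at most 0.5.
#' @return list with merged `labels` and `merges` (data.frame of the merge
#'   steps performed).
#' @export
merge_similar <- function(labels, x, threshold = 0.985,
                          tolerance_identity = FALSE) {
  if (length(labels) != nrow(x)) stop("one label per cell required")
  merges <- data.frame(kept = integer(0), absorbed = integer(0),
                       identity = numeric(0))
  repeat {
    cls <- sort(unique(labels))
    if (length(cls) < 2) break
    med <- cluster_medians(x, labels)
    best <- c(NA, NA); best_id <- -1
    for (a in seq_along(cls)) for (b in seq_len(a - 1)) {
      id <- if (tolerance_identity) {
        mean(abs(med[a, ] - med[b, ]) <= 0.5)
      } else {
        mean(round(med[a, ]) == round(med[b, ]))
      }
      if (id > best_id) { best_id <- id; best <- c(cls[a], cls[b]) }
    }
    if (best_id < threshold) break
    keep <- min(best); absorb <- max(best)
    labels[labels == absorb] <- keep
    merges <- rbind(merges, data.frame(kept = keep, absorbed = absorb,
                                       identity = best_id))
  }
  # renumber by decreasing size
  sizes <- sort(table(labels), decreasing = TRUE)
  labels <- match(as.character(labels), names(sizes))
  list(labels = labels, merges = merges)
}

#' Discover subpopulations among non-replicating cells
#'
#' Appends the five calibration cells, embeds to 2-D with UMAP, derives the
#' DBSCAN radius with [epsilon_from_embedding()] and clusters with
#' `min_samples = max(round(min_samples_frac * n_cells), min_cells)`. The
#' embedding + clustering is repeated with six auxiliary seeds drawn from
#' \[3, 2^30\]; the modal cluster count across the seven runs is retained
#' (the first auxiliary seed achieving it replaces the master seed if
#' needed). Noise points are attached to the nearest cluster centroid,
#' calibration cells are removed, clusters with fewer than `min_cells`
#' real cells are dissolved into their nearest cluster, and near-identical
#' clusters are merged with [merge_similar()].
#'
#' @param m complete copy-number matrix of non-replicating cells (run after
#'   imputation); only autosomal bins are used as features.
#' @param seed master seed (default 18671107).
#' @param min_samples_frac DBSCAN `min_samples` as a fraction of the cell
#'   count.
#' @param min_cells minimum number of cells per subpopulation.
#' @param merge_threshold identity threshold for [merge_similar()].
#' @param n_seeds number of auxiliary voting seeds.
#' @param literal_epsilon see [epsilon_from_embedding()].
#' @param calibration append the five constant-ploidy calibration cells.
#' @return object of class `subpop_assignment`: per-cell `labels` (named
#'   integer vector), `embedding` (2-D coordinates of real cells),
#'   `calibration_embedding`, `epsilon`, `min_samples`, `votes` (cluster
#'   count per seed), `seed_used`, `merges` and per-cluster `medians`.
#' @export
discover_g1_subpopulations <- function(m, seed = DEFAULT_SEED,
                                       min_samples_frac = 0.10,
                                       min_cells = 10,
                                       merge_threshold = 0.985,
                                       n_seeds = 6,
                                       literal_epsilon = FALSE,
                                       calibration = TRUE) {
  validate_cn_matrix(m)
  if (anyNA(m)) stop("matrix contains missing values; impute first")
  feats <- m[, autosomal_columns(m), drop = FALSE]
  n_real <- nrow(feats)
  if (n_real < 20) stop("need at least 20 non-replicating cells")
  feats_all <- if (calibration) rbind(feats, calibration_profiles(colnames(feats))) else feats
  min_samples <- max(round(min_samples_frac * n_real), min_cells)
  if (n_real < min_samples) stop("fewer cells than DBSCAN min_samples")

  aux_seeds <- withr::with_seed(seed, as.integer(floor(stats::runif(n_seeds, 3, 2^30))))
  seeds <- c(as.integer(seed), aux_seeds)
  runs <- lapply(seeds, function(s) {
    emb <- umap_embed(feats_all, 2, s)
    eps <- epsilon_from_embedding(emb, literal = literal_epsilon)
    labels <- dbscan_cluster(emb, eps, min_samples)
    list(seed = s, embedding = emb, epsilon = eps, labels = labels,
         k = length(unique(labels[labels > 0L])))
  })
  votes <- vapply(runs, function(r) r$k, 1L)
  tab <- table(votes)
  modal <- as.integer(names(tab)[tab == max(tab)])
  chosen <- if (votes[1] %in% modal) 1L else which(votes %in% modal)[1]
  run <- runs[[chosen]]
  if (run$k == 0) stop("all points classified as noise; no subpopulation found")

  labels <- attach_noise(run$labels, run$embedding)
  real_labels <- labels[seq_len(n_real)]
  # dissolve clusters that fall below the minimum real-cell size
  repeat {
    sizes <- table(real_labels)
    small <- names(sizes)[sizes < min_cells]
    if (length(small) == 0 || length(sizes) == 1) break
    k_small <- as.integer(small[1])
    keep_cls <- setdiff(unique(real_labels), k_small)
    cent <- t(vapply(keep_cls, function(k) {
      colMeans(run$embedding[seq_len(n_real)[real_labels == k], , drop = FALSE])
    }, numeric(2)))
    for (i in which(real_labels == k_small)) {
      d2 <- rowSums(sweep(cent, 2, run$embedding[i, ], "-")^2)
      real_labels[i] <- keep_cls[which.min(d2)]
    }
  }
  merged <- merge_similar(real_labels, feats, threshold = merge_threshold)
  real_labels <- merged$labels
  names(real_labels) <- rownames(feats)
  structure(list(labels = real_labels,
                 embedding = run$embedding[seq_len(n_real), , drop = FALSE],
                 calibration_embedding = if (calibration)
                   run$embedding[-seq_len(n_real), , drop = FALSE] else NULL,
                 epsilon = run$epsilon, min_samples = min_samples,
                 votes = data.frame(seed = seeds, k = votes),
                 seed_used = run$seed, merges = merged$merges,
                 medians = cluster_medians(feats, real_labels)),
            class = "subpop_assignment")
}

#' @export
print.subpop_assignment <- function(x, ...) {
  k <- length(unique(x$labels))
  cat(sprintf("Subpopulation assignment: %d cells in %d subpopulation(s)\n",
              length(x$labels), k))
  cat(sprintf("  epsilon = %.4g, min_samples = %d, seed used = %d\n",
              x$epsilon, x$min_samples, x$seed_used))
  print(table(subpopulation = x$labels))
  invisible(x)
}

#' Match replicating cells to discovered subpopulations
#'
#' Embeds all cells (plus calibration cells) to ten UMAP dimensions and
#' assigns each replicating cell the majority subpopulation label of its
#' `max(round(0.5 * n_G1), 5)` nearest non-replicating neighbours
#' (Euclidean distance in the embedding). Ties break towards the nearest
#' neighbour's label.
#'
#' @param m complete copy-number matrix of all cells (replicating and
#'   non-replicating).
#' @param replicating logical per-cell replication state, in `m`'s row
#'   order (or a character vector of "S"/"G1" phases).
#' @param g1_assignment a `subpop_assignment` covering the non-replicating
#'   cells of `m`.
#' @param seed seed for the 10-D embedding.
#' @param calibration append calibration cells to the embedding.
#' @return object of class `subpop_assignment` with labels for every cell
#'   and the 10-D embedding in `embedding10`.
#' @export
match_replicating <- function(m, replicating, g1_assignment,
                              seed = DEFAULT_SEED, calibration = TRUE) {
  validate_cn_matrix(m)
  repl <- as_replicating(replicating)
  if (length(repl) != nrow(m)) stop("one replication state per cell required")
  g1_cells <- names(g1_assignment$labels)
  if (!all(rownames(m)[!repl] %in% g1_cells)) {
    stop("g1_assignment does not cover all non-replicating cells")
  }
  if (!any(!repl)) stop("no non-replicating cells to match against")
  labels <- rep(NA_integer_, nrow(m))
  names(labels) <- rownames(m)
  labels[!repl] <- g1_assignment$labels[rownames(m)[!repl]]
  if (!any(repl)) {
    out <- g1_assignment
    out$labels <- labels
    return(out)
  }
  feats <- m[, autosomal_columns(m), drop = FALSE]
  feats_all <- if (calibration) rbind(feats, calibration_profiles(colnames(feats))) else feats
  emb <- umap_embed(feats_all, 10, seed)
  emb_real <- emb[seq_len(nrow(m)), , drop = FALSE]
  g1_idx <- which(!repl)
  k <- max(round(0.5 * length(g1_idx)), 5)
  k <- min(k, length(g1_idx))
  g1_emb <- emb_real[g1_idx, , drop = FALSE]
  g1_lab <- labels[g1_idx]
  for (i in which(repl)) {
    d2 <- rowSums(sweep(g1_emb, 2, emb_real[i, ], "-")^2)
    nn <- order(d2)[seq_len(k)]
    counts <- table(g1_lab[nn])
    top <- names(counts)[counts == max(counts)]
    labels[i] <- if (length(top) == 1) as.integer(top)
                 else g1_lab[nn[which(as.character(g1_lab[nn]) %in% top)[1]]]
  }
  structure(list(labels = labels,
                 embedding = g1_assignment$embedding,
                 embedding10 = emb_real,
                 calibration_embedding = g1_assignment$calibration_embedding,
                 epsilon = g1_assignment$epsilon,
                 min_samples = g1_assignment$min_samples,
                 votes = g1_assignment$votes,
                 seed_used = g1_assignment$seed_used,
                 merges = g1_assignment$merges,
                 medians = g1_assignment$medians,
                 n_neighbors = k),
            class = "subpop_assignment")
}

#' Full subpopulation discovery for a mixed cohort
#'
#' Convenience wrapper: discovers subpopulations among the non-replicating
#' cells and matches the replicating cells to them.
#'
#' @param m complete copy-number matrix of all cells.
#' @param replicating per-cell replication states (logical or "S"/"G1").
#' @param seed master seed.
#' @param ... passed to [discover_g1_subpopulations()].
#' @return a `subpop_assignment` covering every cell.
#' @export
subpopulations <- function(m, replicating, seed = DEFAULT_SEED, ...) {
  repl <- as_replicating(replicating)
  g1 <- discover_g1_subpopulations(m[!repl, , drop = FALSE], seed = seed, ...)
  match_replicating(m, repl, g1, seed = seed)
}
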