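# Synthetic single-cell copy-number cohorts.
#
# The generator states a simple world with the statistical structure the
# pipeline assumes: clonal populations with integer karyotypes, sporadic
# +/-1 copy noise, uniformly random missingness, S-phase cells whose bins
# double in a fixed replication-timing order, and barcode read counts drawn
# from a two-component log-normal mixture. Truth labels are returned so
# that every downstream stage can be scored against the planted structure.

#' Default synthetic chromosome sizes
#'
#' A reduced genome of `n_chrom` autosomes of `chrom_length` bases each
#' (default 5 x 20 Mb, i.e. 1000 bins of 100 kb), keeping simulations fast
#' while leaving room for whole-chromosome karyotype differences.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length length of each chromosome in bases.
#' @return data.frame with columns `chrom`, `size`.
#' @export
default_chrom_sizes <- function(n_chrom = 5, chrom_length = 2e7) {
  data.frame(chrom = paste0("chr", seq_len(n_chrom)), size = chrom_length)
}

#' Describe a clonal population
#'
#' @param name clone label used in cell identifiers and truth tables.
#' @param karyotype either a named numeric vector of integer copy numbers,
#'   one entry per chromosome (e.g. `c(chr1 = 2, chr2 = 3)`), or an
#'   unnamed per-bin vector matching the bin index the clone will be
#'   generated on (for sub-chromosomal alterations).
#' @param n_cells number of cells in the clone.
#' @param noise_rate fraction of bins per cell receiving independent +/-1
#'   copy noise (clipped at 0).
#' @return object of class `clone_spec`.
#' @export
clone_spec <- function(name, karyotype, n_cells, noise_rate = 0.05) {
  stopifnot(is.character(name), length(name) == 1)
  per_bin <- is.null(names(karyotype))
  if (!per_bin && any(!nzchar(names(karyotype)))) {
    stop("'karyotype' must be fully named (per chromosome) or unnamed (per bin)")
  }
  if (any(karyotype < 0) || any(karyotype != round(karyotype))) {
    stop("karyotype copy numbers must be integers >= 0")
  }
  if (n_cells < 1) stop("'n_cells' must be >= 1")
  if (noise_rate < 0 || noise_rate > 1) stop("'noise_rate' must be in [0, 1]")
  structure(list(name = name, karyotype = karyotype,
                 n_cells = as.integer(n_cells), noise_rate = noise_rate),
            class = "clone_spec")
}

# Expand a per-chromosome (or pass through a per-bin) karyotype to a
# per-bin profile.
karyotype_profile <- function(clone, bins) {
  if (is.null(names(clone$karyotype))) {
    if (length(clone$karyotype) != nrow(bins)) {
      stop("clone '", clone$name, "': per-bin karyotype has length ",
           length(clone$karyotype), " but there are ", nrow(bins), " bins")
    }
    return(as.numeric(clone$karyotype))
  }
  missing_chr <- setdiff(unique(bins$chrom), names(clone$karyotype))
  if (length(missing_chr)) {
    stop("clone '", clone$name, "' karyotype does not cover: ",
         paste(missing_chr, collapse = ", "))
  }
  as.numeric(clone$karyotype[bins$chrom])
}

# +/-1 noise on an exact round(rate * n_bins) count of bins per cell,
# equal sign probability, clipped at 0. Operates on a cells x bins matrix.
apply_cn_noise <- function(m, rate) {
  n_alter <- round(rate * ncol(m))
  if (n_alter == 0) return(m)
  for (i in seq_len(nrow(m))) {
    pos <- sample.int(ncol(m), n_alter)
    m[i, pos] <- pmax(m[i, pos] + sample(c(-1, 1), n_alter, replace = TRUE), 0)
  }
  m
}

#' Generate non-replicating (G1) cells from clone specifications
#'
#' Each cell's profile equals its clone karyotype expanded over `bins`,
#' with +/-1 noise applied to a `noise_rate` fraction of bins. No missing
#' values are produced (missingness is introduced only by [mask_random()]).
#'
#' @param clones list of [clone_spec()] objects (a single spec is accepted).
#' @param bins bin index data.frame (see [make_bins()]).
#' @param seed optional integer seed.
#' @return list with `matrix` (cells x bins) and `labels` (data.frame
#'   `cell`, `clone`).
#' @export
make_g1_population <- function(clones, bins, seed = NULL) {
  if (inherits(clones, "clone_spec")) clones <- list(clones)
  if (length(clones) == 0) stop("empty clone list")
  if (nrow(bins) == 0) stop("'bins' must be non-empty")
  if (!is.null(seed)) withr::local_seed(seed)
  regions <- region_names(bins)
  mats <- vector("list", length(clones))
  labs <- vector("list", length(clones))
  for (ci in seq_along(clones)) {
    cl <- clones[[ci]]
    prof <- karyotype_profile(cl, bins)
    m <- matrix(rep(prof, each = cl$n_cells), nrow = cl$n_cells)
    m <- apply_cn_noise(m, cl$noise_rate)
    rownames(m) <- sprintf("%s_G1_%04d", cl$name, seq_len(cl$n_cells))
    mats[[ci]] <- m
    labs[[ci]] <- data.frame(cell = rownames(m), clone = cl$name,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, mats)
  colnames(out) <- regions
  list(matrix = out, labels = do.call(rbind, labs))
}

#' Generate a replication-timing ordering of bins
#'
#' A uniformly random permutation of the bins standing in for a replication
#' programme: position 1 replicates earliest.
#'
#' @param bins bin index data.frame.
#' @param seed optional integer seed.
#' @return integer vector of bin indices, earliest to latest.
#' @export
make_rt_order <- function(bins, seed = NULL) {
  if (nrow(bins) == 0) stop("'bins' must be non-empty")
  if (!is.null(seed)) withr::local_seed(seed)
  sample.int(nrow(bins))
}

#' Generate replicating (S-phase) cells for one clone
#'
#' Each cell draws a replication progress `p` from `progress_range`; the
#' earliest `round(p * n_bins)` bins of `rt_order` carry twice the clone's
#' karyotype copy number and the rest the karyotype value, after which
#' clone noise is applied as in [make_g1_population()].
#'
#' @param clone a [clone_spec()].
#' @param rt_order integer bin ordering from [make_rt_order()].
#' @param n_cells number of S cells to generate.
#' @param bins bin index data.frame.
#' @param progress_range interval within (0, 1) from which per-cell
#'   progress is drawn uniformly.
#' @param seed optional integer seed.
#' @return list with `matrix` (cells x bins) and `labels` (data.frame
#'   `cell`, `clone`, `progress`).
#' @export
make_s_population <- function(clone, rt_order, n_cells, bins,
                              progress_range = c(0.05, 0.95), seed = NULL) {
  if (length(rt_order) == 0) stop("'rt_order' covers no bins")
  if (length(rt_order) != nrow(bins) || !setequal(rt_order, seq_len(nrow(bins)))) {
    stop("'rt_order' must be a permutation of the bins")
  }
  if (any(progress_range < 0) || any(progress_range > 1)) {
    stop("'progress_range' must lie within [0, 1]")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  prof <- karyotype_profile(clone, bins)
  p <- stats::runif(n_cells, progress_range[1], progress_range[2])
  m <- matrix(rep(prof, each = n_cells), nrow = n_cells)
  for (i in seq_len(n_cells)) {
    n_rep <- round(p[i] * length(rt_order))
    if (n_rep > 0) {
      repl <- rt_order[seq_len(n_rep)]
      m[i, repl] <- 2 * m[i, repl]
    }
  }
  m <- apply_cn_noise(m, clone$noise_rate)
  rownames(m) <- sprintf("%s_S_%04d", clone$name, seq_len(n_cells))
  colnames(m) <- region_names(bins)
  list(matrix = m,
       labels = data.frame(cell = rownames(m), clone = clone$name,
                           progress = p, stringsAsFactors = FALSE))
}

#' Mask matrix entries uniformly at random
#'
#' Sets exactly `round(fraction * n_entries)` entries to missing, uniformly
#' at random, and returns their positions for later evaluation.
#'
#' @param m copy-number matrix with no pre-existing missing values.
#' @param fraction proportion of entries to mask, strictly in (0, 1).
#' @param seed optional integer seed.
#' @return list with `matrix` (masked), `mask` (data.frame `row`, `col`)
#'   and `fraction`.
#' @export
mask_random <- function(m, fraction, seed = NULL) {
  if (fraction <= 0 || fraction >= 1) stop("'fraction' must be strictly between 0 and 1")
  if (anyNA(m)) stop("matrix already contains missing values")
  if (!is.null(seed)) withr::local_seed(seed)
  n_mask <- round(fraction * length(m))
  idx <- sample.int(length(m), n_mask)
  pos <- arrayInd(idx, dim(m))
  m[idx] <- NA_real_
  list(matrix = m,
       mask = data.frame(row = pos[, 1], col = pos[, 2]),
       fraction = fraction)
}

#' Simulate per-barcode read counts from a two-component log-normal mixture
#'
#' Valid barcodes (true cells) draw more reads than invalid ones
#' (ambient/corrupted barcodes); truth labels are retained for evaluation.
#' Defaults place the invalid mode around 40k reads and the valid mode
#' around 200k reads, both above the usual 30k prefilter so the mixture fit
#' is exercised.
#'
#' @param n_valid,n_invalid component sizes.
#' @param mu_invalid,sigma_invalid log-scale location/scale of the invalid
#'   (lower) component.
#' @param mu_valid,sigma_valid log-scale location/scale of the valid
#'   component; `mu_valid` must exceed `mu_invalid`.
#' @param seed optional integer seed.
#' @return data.frame with columns `barcode`, `reads`, `valid` (truth).
#' @export
make_barcode_counts <- function(n_valid, n_invalid,
                                mu_invalid = 10.6, sigma_invalid = 0.2,
                                mu_valid = 12.2, sigma_valid = 0.3,
                                seed = NULL) {
  if (sigma_invalid <= 0 || sigma_valid <= 0) stop("sigma parameters must be > 0")
  if (mu_valid <= mu_invalid) stop("'mu_valid' must exceed 'mu_invalid'")
  if (!is.null(seed)) withr::local_seed(seed)
  reads <- round(c(stats::rlnorm(n_invalid, mu_invalid, sigma_invalid),
                   stats::rlnorm(n_valid, mu_valid, sigma_valid)))
  valid <- rep(c(FALSE, TRUE), c(n_invalid, n_valid))
  ord <- sample.int(length(reads))
  data.frame(barcode = sprintf("BC%05d", seq_along(reads)),
             reads = reads[ord], valid = valid[ord],
             stringsAsFactors = FALSE)
}

#' Simulate a complete mixed cohort
#'
#' Convenience wrapper generating, for each clone, G1 cells and a fraction
#' of S-phase cells replicating in a shared random RT order.
#'
#' @param clones list of [clone_spec()] objects.
#' @param bins bin index data.frame.
#' @param s_fraction fraction of each clone's cells that are replicating.
#' @param progress_range per-cell S-phase progress interval.
#' @param rt_order optional fixed RT ordering (defaults to a seeded random
#'   permutation).
#' @param seed optional integer seed.
#' @return list with `matrix` (all cells x bins), `truth` (data.frame
#'   `cell`, `clone`, `phase`, `progress`) and `rt_order`.
#' @export
simulate_cohort <- function(clones, bins, s_fraction = 0.25,
                            progress_range = c(0.05, 0.95),
                            rt_order = NULL, seed = NULL) {
  if (inherits(clones, "clone_spec")) clones <- list(clones)
  if (!is.null(seed)) withr::local_seed(seed)
  if (is.null(rt_order)) rt_order <- make_rt_order(bins)
  mats <- list(); truths <- list()
  for (cl in clones) {
    n_s <- round(s_fraction * cl$n_cells)
    n_g1 <- cl$n_cells - n_s
    if (n_g1 > 0) {
      g1 <- make_g1_population(clone_spec(cl$name, cl$karyotype, n_g1, cl$noise_rate), bins)
      mats[[length(mats) + 1]] <- g1$matrix
      truths[[length(truths) + 1]] <- data.frame(g1$labels, phase = "G1",
                                                 progress = NA_real_)
    }
    if (n_s > 0) {
      s <- make_s_population(cl, rt_order, n_s, bins, progress_range)
      mats[[length(mats) + 1]] <- s$matrix
      truths[[length(truths) + 1]] <- data.frame(cell = s$labels$cell,
                                                 clone = s$labels$clone,
                                                 phase = "S",
                                                 progress = s$labels$progress)
    }
  }
  list(matrix = do.call(rbind, mats),
       truth = do.call(rbind, truths),
       rt_order = rt_order)
}

#' Write a simulated cohort to disk
#'
#' Emits the BED-like copy-number table consumed by [read_cn()] plus a
#' truth-labels TSV (`cell_id`, `clone`, `phase`, `progress`).
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cn_path <- file.path(dir, "copy_numbers.bed")
  truth_path <- file.path(dir, "truth.tsv")
  write_cn(cohort$matrix, cn_path, layout = "bed")
  truth <- cohort$truth
  names(truth)[names(truth) == "cell"] <- "cell_id"
  data.table::fwrite(truth, truth_path, sep = "\t", na = "NA", quote = FALSE)
  c(copy_numbers = cn_path, truth = truth_path)
}
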