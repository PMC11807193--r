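# Validation scenarios.
#
# These builders state, once, the synthetic worlds on which the package's
# headline validation experiments run: a 1288-bin genome (14 autosomes of
# 9.2 Mb at 100 kb resolution, matching the matrix size of the imputation
# benchmark), clone mixtures with whole-chromosome and sub-chromosomal
# differences, 5% sporadic +/-1 copy noise, and S-phase fractions around a
# quarter of each population. The acceptance tests and the acceptance
# report script both consume these functions so that the measured numbers
# come from one stated world.

#' Chromosome sizes of the validation genome
#'
#' Fourteen autosomes of 9.2 Mb: 92 bins of 100 kb each, 1288 bins total.
#'
#' @return data.frame with columns `chrom`, `size`.
#' @export
validation_chrom_sizes <- function() {
  default_chrom_sizes(n_chrom = 14, chrom_length = 9.2e6)
}

#' Replication-timing programme of the validation genome
#'
#' A fixed ordering of the validation genome's 1288 bins from earliest- to
#' latest-replicating. The RT programme is a property of the genome, shared
#' by every validation cohort, exactly as real RT programmes are broadly
#' conserved across human cell types -- which is what lets a classifier
#' trained on one cohort generalise to another.
#'
#' @return integer vector: bin indices, earliest to latest.
#' @export
validation_rt_order <- function() {
  make_rt_order(make_bins(validation_chrom_sizes()), seed = 18671107L)
}

#' Classifier validation cohort
#'
#' Three karyotype-distinct clones (diploid; triploid with six additional
#' whole-chromosome gains; diploid with three sub-chromosomal gains of 20
#' bins each), 400 cells per clone of which half are S-phase cells
#' replicating a shared random RT order with progress Uniform(0.05, 0.95);
#' 5% noise. Yields ~600 G1 and ~600 S cells.
#'
#' @param seed integer seed.
#' @param noise_rate per-cell fraction of noisy bins.
#' @return a [simulate_cohort()] result.
#' @export
validation_cohort_classifier <- function(seed, noise_rate = 0.05) {
  bins <- make_bins(validation_chrom_sizes())
  chroms <- validation_chrom_sizes()$chrom
  base_diploid <- stats::setNames(rep(2, length(chroms)), chroms)
  triploid <- stats::setNames(rep(3, length(chroms)), chroms)
  triploid[1:6] <- 4  # six whole-chromosome gains on top of triploidy
  subgain <- rep(2, nrow(bins))
  for (start in c(10, 300, 700)) subgain[start:(start + 19)] <- 3
  clones <- list(
    clone_spec("diploid", base_diploid, 400, noise_rate),
    clone_spec("triploid_gains", triploid, 400, noise_rate),
    clone_spec("subchromosomal", subgain, 400, noise_rate))
  simulate_cohort(clones, bins, s_fraction = 0.5,
                  rt_order = validation_rt_order(), seed = seed)
}

#' Two-clone imputation validation matrix
#'
#' 2000 cells x 1288 bins: a diploid clone (1000 cells) and an aneuploid
#' clone (1000 cells) carrying eight whole-chromosome gains, with 5%
#' within-clone noise. Like the cell population on which the imputation
#' benchmark was originally run, the sample is an S-phase-enriched mixture
#' of replicating and non-replicating cells (60% S cells per clone,
#' replicating a shared RT order with progress Uniform(0.05, 0.95)), and
#' the two subpopulations are near-even.
#'
#' @param seed integer seed.
#' @param noise_rate per-cell fraction of noisy bins.
#' @param n_per_clone cells per clone (default 1000; smaller values give a
#'   scaled-down matrix with the same structure).
#' @return complete cells x bins matrix (no missing values).
#' @export
validation_matrix_imputation <- function(seed, noise_rate = 0.05,
                                         n_per_clone = 1000) {
  bins <- make_bins(validation_chrom_sizes())
  chroms <- validation_chrom_sizes()$chrom
  diploid <- stats::setNames(rep(2, length(chroms)), chroms)
  aneuploid <- diploid
  aneuploid[1:8] <- 3
  co <- simulate_cohort(
    list(clone_spec("diploid", diploid, n_per_clone, noise_rate),
         clone_spec("aneuploid", aneuploid, n_per_clone, noise_rate)),
    bins, s_fraction = 0.6, rt_order = validation_rt_order(), seed = seed)
  co$matrix
}

#' Two-population unmixing validation cohort
#'
#' Population A: near-diploid (one whole-chromosome loss), 1450 cells.
#' Population B: hyperdiploid with eight whole-chromosome gains, 750
#' cells. About 25% of each population is replicating; 5% noise.
#'
#' @param seed integer seed.
#' @param noise_rate per-cell fraction of noisy bins.
#' @return a [simulate_cohort()] result.
#' @export
validation_cohort_unmixing <- function(seed, noise_rate = 0.05) {
  bins <- make_bins(validation_chrom_sizes())
  chroms <- validation_chrom_sizes()$chrom
  near_diploid <- stats::setNames(rep(2, length(chroms)), chroms)
  near_diploid["chr14"] <- 1
  hyperdiploid <- stats::setNames(rep(2, length(chroms)), chroms)
  hyperdiploid[1:8] <- 3
  clones <- list(
    clone_spec("popA", near_diploid, 1450, noise_rate),
    clone_spec("popB", hyperdiploid, 750, noise_rate))
  simulate_cohort(clones, bins, s_fraction = 0.25,
                  rt_order = validation_rt_order(), seed = seed)
}

#' Minor-clone detection sample
#'
#' 100 non-replicating cells: a dominant diploid clone of `100 - s` cells
#' and a minor clone of `s` cells differing by ten whole-chromosome copy
#' numbers, with 2% noise.
#'
#' @param s minor-clone size in cells.
#' @param seed integer seed.
#' @return a [make_g1_population()] result.
#' @export
validation_minor_clone_sample <- function(s, seed) {
  bins <- make_bins(validation_chrom_sizes())
  chroms <- validation_chrom_sizes()$chrom
  diploid <- stats::setNames(rep(2, length(chroms)), chroms)
  minor <- diploid
  minor[1:10] <- 3
  make_g1_population(
    list(clone_spec("dominant", diploid, 100 - s, 0.02),
         clone_spec("minor", minor, s, 0.02)),
    bins, seed = seed)
}
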