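# Shared fixtures: tiny genomes and cohorts built in code.

tiny_sizes <- function() default_chrom_sizes(n_chrom = 2, chrom_length = 1e6)
tiny_bins <- function() make_bins(tiny_sizes(), 1e5)  # 20 bins

# 5 chr x 2 Mb: 100 bins of 100 kb, enough for classifier toys.
toy_bins <- function() make_bins(default_chrom_sizes(5, 2e6), 1e5)

diploid_karyotype <- function(n_chrom = 2) {
  stats::setNames(rep(2, n_chrom), paste0("chr", seq_len(n_chrom)))
}

# Small two-clone G1 cohort on the tiny genome.
tiny_two_clones <- function(n_per = 30, noise = 0.05, seed = 42) {
  kA <- diploid_karyotype()
  kB <- c(chr1 = 3, chr2 = 2)
  make_g1_population(list(clone_spec("A", kA, n_per, noise),
                          clone_spec("B", kB, n_per, noise)),
                     tiny_bins(), seed = seed)
}

# Mixed-phase cohort on a mid-sized genome (14 chr x 2 Mb = 280 bins) with
# two karyotype-distinct populations, for subpopulation/matching tests.
mid_mixed_cohort <- function(nA = 200, nB = 100, s_fraction = 0.25, seed = 7) {
  sizes <- default_chrom_sizes(14, 2e6)
  bins <- make_bins(sizes, 1e5)
  chroms <- sizes$chrom
  kA <- stats::setNames(rep(2, 14), chroms)
  kB <- kA; kB[1:8] <- 3
  clones <- list()
  if (nA > 0) clones <- c(clones, list(clone_spec("A", kA, nA, 0.05)))
  if (nB > 0) clones <- c(clones, list(clone_spec("B", kB, nB, 0.05)))
  simulate_cohort(clones, bins, s_fraction = s_fraction, seed = seed)
}
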