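# Subpopulation discovery: epsilon rule, DBSCAN, merging, matching.

test_that("epsilon follows the range-ratio rule with its clamp", {
  mk <- function(r1, r2) cbind(c(0, r1), c(0, r2))
  expect_equal(epsilon_from_embedding(mk(3, 2)), 1.875)
  expect_equal(epsilon_from_embedding(mk(20, 2)), 2)     # 12.5 clamped down
  expect_equal(epsilon_from_embedding(mk(1, 2)), 1.25)   # 0.625 clamped up
  expect_error(epsilon_from_embedding(cbind(c(0, 1), c(1, 1))), "zero range")
  expect_error(epsilon_from_embedding(mk(1, 1)[1, , drop = FALSE]), "2 points")
  # literal printed variant mixes the axes in the denominator
  coords <- cbind(c(1, 4), c(2, 8))  # range1 = 3, max2 - min1 = 7
  expect_equal(epsilon_from_embedding(coords, literal = TRUE),
               min(max(3 / 7 * 1.25, 1.25), 2))
})

test_that("DBSCAN finds dense groups and marks sparse points as noise", {
  set.seed(70)
  blob1 <- cbind(rnorm(20, 0, 0.1), rnorm(20, 0, 0.1))
  blob2 <- cbind(rnorm(15, 10, 0.1), rnorm(15, 10, 0.1))
  outlier <- matrix(c(5, 5), 1)
  coords <- rbind(blob1, blob2, outlier)
  labels <- dbscan_cluster(coords, eps = 1, min_samples = 5)
  expect_equal(length(unique(labels[1:20])), 1)
  expect_equal(length(unique(labels[21:35])), 1)
  expect_false(labels[1] == labels[21])
  expect_equal(labels[36], 0L)  # noise
  # min_samples above the blob sizes: everything is noise
  expect_true(all(dbscan_cluster(coords, eps = 1, min_samples = 30) == 0L))
})

test_that("merging is driven by rounded-median identity", {
  p <- 200
  regions <- region_names(data.frame(chrom = "chr1", start = (0:(p - 1)) * 1e5,
                                     end = (1:p) * 1e5))
  base <- matrix(2, 40, p, dimnames = list(sprintf("c%02d", 1:40), regions))
  labels <- rep(1:2, each = 20)
  # identical medians merge into one cluster
  res <- merge_similar(labels, base)
  expect_equal(length(unique(res$labels)), 1)
  expect_equal(res$merges$identity, 1)
  # 5% differing bins (identity 0.95) stays below the threshold
  far <- base; far[21:40, 1:10] <- 4
  res2 <- merge_similar(labels, far)
  expect_equal(length(unique(res2$labels)), 2)
  # 1% differing bins merges at the default 98.5% threshold
  near <- base; near[21:40, 1:2] <- 4
  res3 <- merge_similar(labels, near)
  expect_equal(length(unique(res3$labels)), 1)
})

# Exhaustive merge-order oracle: try all merge orders among qualifying
# pairs and return the set of reachable final cluster counts.
merge_oracle <- function(labels, x, threshold) {
  identity <- function(a, b, labs) {
    ma <- apply(x[labs == a, , drop = FALSE], 2, median)
    mb <- apply(x[labs == b, , drop = FALSE], 2, median)
    mean(round(ma) == round(mb))
  }
  explore <- function(labs) {
    cls <- sort(unique(labs))
    pairs <- list()
    if (length(cls) > 1) {
      for (a in seq_along(cls)) for (b in seq_len(a - 1)) {
        if (identity(cls[a], cls[b], labs) >= threshold) {
          pairs[[length(pairs) + 1]] <- c(cls[a], cls[b])
        }
      }
    }
    if (length(pairs) == 0) return(length(cls))
    unlist(lapply(pairs, function(pr) {
      labs2 <- labs
      labs2[labs2 == pr[1]] <- pr[2]
      explore(labs2)
    }))
  }
  unique(explore(labels))
}

test_that("iterative merging is order-invariant on chained clusters", {
  p <- 100
  regions <- region_names(data.frame(chrom = "chr1", start = (0:(p - 1)) * 1e5,
                                     end = (1:p) * 1e5))
  x <- matrix(2, 30, p, dimnames = list(sprintf("c%02d", 1:30), regions))
  x[11:20, 1] <- 4   # B differs from A on 1 bin (identity 0.99)
  x[21:30, 1:2] <- 4 # C differs from A on 2 bins, from B on 1 bin
  labels <- rep(1:3, each = 10)
  res <- merge_similar(labels, x, threshold = 0.985)
  oracle_counts <- merge_oracle(labels, x, 0.985)
  expect_equal(length(oracle_counts), 1)  # every merge order agrees
  expect_equal(length(unique(res$labels)), oracle_counts)
  # chaining is stopped by median recomputation: A+B drifts away from C
  expect_equal(length(unique(res$labels)), 2)
  # pairwise-identical medians do collapse to a single cluster
  y <- x; y[11:30, ] <- 2
  res_all <- merge_similar(labels, y, threshold = 0.985)
  expect_equal(length(unique(res_all$labels)), 1)
  expect_equal(merge_oracle(labels, y, 0.985), 1)
})

test_that("a homogeneous clone yields a single subpopulation", {
  sizes <- default_chrom_sizes(14, 2e6)
  bins <- make_bins(sizes, 1e5)
  karyo <- stats::setNames(rep(2, 14), sizes$chrom)
  pop <- make_g1_population(clone_spec("A", karyo, 200, 0.05), bins, seed = 71)
  asg <- discover_g1_subpopulations(pop$matrix)
  expect_equal(length(unique(asg$labels)), 1)
  expect_true(asg$epsilon >= 1.25 && asg$epsilon <= 2)
  expect_equal(nrow(asg$votes), 7)
})

test_that("two karyotype-distinct clones are recovered exactly", {
  co <- mid_mixed_cohort(nA = 150, nB = 150, s_fraction = 0, seed = 72)
  asg <- discover_g1_subpopulations(co$matrix)
  expect_equal(length(unique(asg$labels)), 2)
  truth <- co$truth$clone[match(names(asg$labels), co$truth$cell)]
  expect_equal(length(unique(paste(asg$labels, truth))), 2)  # perfect split
  # labels partition the cells
  expect_equal(sum(table(asg$labels)), nrow(co$matrix))
})

test_that("the ten-cell floor separates reportable subpopulations", {
  pop9 <- validation_minor_clone_sample(9, seed = 73)
  asg9 <- discover_g1_subpopulations(pop9$matrix)
  expect_equal(length(unique(asg9$labels)), 1)
  pop10 <- validation_minor_clone_sample(10, seed = 73)
  asg10 <- discover_g1_subpopulations(pop10$matrix)
  expect_equal(length(unique(asg10$labels)), 2)
})

test_that("discovery is reproducible and validates its input", {
  co <- mid_mixed_cohort(nA = 60, nB = 40, s_fraction = 0, seed = 74)
  a1 <- discover_g1_subpopulations(co$matrix)
  a2 <- discover_g1_subpopulations(co$matrix)
  expect_identical(a1$labels, a2$labels)
  expect_identical(a1$embedding, a2$embedding)
  holed <- co$matrix; holed[1, 1] <- NA
  expect_error(discover_g1_subpopulations(holed), "impute first")
  expect_error(discover_g1_subpopulations(co$matrix[1:10, ]), "at least 20")
})

test_that("replicating cells are matched to their clone of origin", {
  # genome-scale bin count: clone separation must dominate the S-phase
  # doubling signal in the embedding
  bins <- make_bins(validation_chrom_sizes())
  chroms <- validation_chrom_sizes()$chrom
  kA <- stats::setNames(rep(2, 14), chroms)
  kB <- kA; kB[1:8] <- 3
  co <- simulate_cohort(list(clone_spec("A", kA, 200, 0.05),
                             clone_spec("B", kB, 100, 0.05)),
                        bins, s_fraction = 0.25,
                        progress_range = c(0.2, 0.4), seed = 75)
  repl <- co$truth$phase[match(rownames(co$matrix), co$truth$cell)] == "S"
  asg <- subpopulations(co$matrix, repl)
  truth <- co$truth$clone[match(names(asg$labels), co$truth$cell)]
  # every cell labelled exactly once, S cells included
  expect_false(anyNA(asg$labels))
  expect_equal(length(asg$labels), nrow(co$matrix))
  # planted-truth recovery for both phases
  tab <- table(asg$labels, truth)
  expect_equal(min(apply(tab, 2, max) / colSums(tab)), 1)
  # neighbour count rule: half the G1 cells
  expect_equal(asg$n_neighbors, round(0.5 * sum(!repl)))
})

test_that("matching falls back to the five-neighbour floor and empty S set", {
  co <- mid_mixed_cohort(nA = 30, nB = 0, s_fraction = 0, seed = 76)
  g1 <- discover_g1_subpopulations(co$matrix)
  # zero S cells: assignment passes through unchanged
  out <- match_replicating(co$matrix, rep(FALSE, 30), g1)
  expect_equal(unname(out$labels), unname(g1$labels[names(out$labels)]))
  # n_G1 = 6 leads to the 5-neighbour floor
  small <- co$matrix[1:10, ]
  g1_small <- structure(list(labels = stats::setNames(rep(1L, 6), rownames(small)[1:6]),
                             embedding = NULL, calibration_embedding = NULL,
                             epsilon = 1.25, min_samples = 10,
                             votes = NULL, seed_used = 1L, merges = NULL,
                             medians = NULL),
                        class = "subpop_assignment")
  out2 <- match_replicating(small, c(rep(FALSE, 6), rep(TRUE, 4)), g1_small)
  expect_equal(out2$n_neighbors, 5)
  expect_true(all(out2$labels == 1L))
})
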