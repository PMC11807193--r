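# Replication-timing utilities.

test_that("binarisation applies the 1.5x baseline rule", {
  regions <- region_names(data.frame(chrom = "chr1", start = c(0, 1e5),
                                     end = c(1e5, 2e5)))
  s <- matrix(c(4, 2, 3, NA), 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), regions))
  b <- binarize_s_cells(s, baseline = c(2, 2))
  expect_equal(unname(b$matrix["s1", ]), c(1, 0))  # ratios 2 and 1
  expect_equal(unname(b$matrix["s2", 1]), 1)       # ratio 1.5 counts
  expect_true(is.na(b$matrix["s2", 2]))            # missing stays missing
  expect_equal(unname(b$progress), c(0.5, 1))
  expect_equal(b$threshold, 1.5)
  expect_error(binarize_s_cells(s, baseline = c(0, 2)), "zero or missing")
  expect_error(binarize_s_cells(s, baseline = 2), "one value per bin")
})

test_that("binarisation recovers the generator's replication progress", {
  bins <- make_bins(default_chrom_sizes(5, 1e7), 1e5)  # 500 bins
  cl <- clone_spec("A", stats::setNames(rep(2, 5), paste0("chr", 1:5)), 40, 0.05)
  rt <- make_rt_order(bins, seed = 80)
  s <- make_s_population(cl, rt, 40, bins, progress_range = c(0.4, 0.4), seed = 81)
  b <- binarize_s_cells(s$matrix, baseline = rep(2, 500))
  # +-1 noise sits exactly on the 1.5x midpoint, so per-cell estimates carry
  # a small upward bias; the mean absolute error stays within 0.02
  expect_lte(mean(abs(b$progress - 0.4)), 0.02)
  # noise-free cells recover progress to rounding resolution
  s0 <- make_s_population(clone_spec("A", stats::setNames(rep(2, 5), paste0("chr", 1:5)), 10, 0),
                          rt, 10, bins, progress_range = c(0.4, 0.4), seed = 82)
  b0 <- binarize_s_cells(s0$matrix, baseline = rep(2, 500))
  expect_true(all(abs(b0$progress - 0.4) <= 1 / 500))
})

test_that("pseudo-bulk RT is the informative-cell fraction", {
  regions <- region_names(data.frame(chrom = "chr1", start = (0:2) * 1e5,
                                     end = (1:3) * 1e5))
  m <- matrix(NA_real_, 10, 3, dimnames = list(sprintf("s%02d", 1:10), regions))
  m[, 1] <- 1
  m[, 2] <- c(rep(1, 3), rep(0, 7))
  rt <- pseudobulk_rt(m)
  expect_equal(unname(rt[1]), 1)
  expect_equal(unname(rt[2]), 0.3)
  expect_true(is.na(rt[3]))  # bin missing in every cell
})

test_that("pseudo-bulk RT is monotone in the planted RT order", {
  bins <- make_bins(default_chrom_sizes(2, 1e7), 1e5)  # 200 bins
  cl <- clone_spec("A", diploid_karyotype(), 120, 0)
  rt_order <- make_rt_order(bins, seed = 82)
  s <- make_s_population(cl, rt_order, 120, bins,
                         progress_range = c(0.05, 0.95), seed = 83)
  profile <- pseudobulk_rt(binarize_s_cells(s$matrix, rep(2, 200)))
  # earlier rank in rt_order -> larger replicated fraction (ties between
  # adjacent ranks keep |rho| marginally below 1)
  rank_of_bin <- order(rt_order)
  expect_lt(cor(profile, rank_of_bin, method = "spearman"), -0.99)
})

test_that("profile correlations and ordering behave as stated", {
  set.seed(84)
  p1 <- runif(300)
  names(p1) <- region_names(data.frame(chrom = "chr1", start = (0:299) * 1e5,
                                       end = (1:300) * 1e5))
  # self-correlation 1; strictly antitone transform -1
  p_rev <- max(p1) - p1 + min(p1)
  res <- correlate_profiles(list(a = p1, b = p_rev, c = p1))
  expect_equal(unname(diag(res$correlation)), rep(1, 3))
  expect_equal(unname(res$correlation["a", "b"]), -1)
  expect_equal(unname(res$correlation["a", "c"]), 1)
  expect_true(isSymmetric(res$correlation))
  # invariance under strictly monotone transforms
  res2 <- correlate_profiles(list(a = p1, d = exp(3 * p1)))
  expect_equal(unname(res2$correlation["a", "d"]), 1)
  expect_equal(sort(res$order), 1:3)
  expect_error(correlate_profiles(list(a = p1)), "two profiles")
})

test_that("shared RT orders correlate while shuffled ones do not", {
  bins <- make_bins(default_chrom_sizes(2, 1e7), 1e5)
  cl <- clone_spec("A", diploid_karyotype(), 80, 0.02)
  rt1 <- make_rt_order(bins, seed = 85)
  rt2 <- make_rt_order(bins, seed = 86)  # independent order
  prof <- function(rt, seed) {
    s <- make_s_population(cl, rt, 80, bins, seed = seed)
    pseudobulk_rt(binarize_s_cells(s$matrix, rep(2, 200)))
  }
  shared1 <- prof(rt1, 87); shared2 <- prof(rt1, 88); other <- prof(rt2, 89)
  cors <- correlate_profiles(list(s1 = shared1, s2 = shared2, o = other))$correlation
  expect_gt(cors["s1", "s2"], 0.95)
  expect_lt(abs(cors["s1", "o"]), 0.2)
})

test_that("permutation test matches exhaustive enumeration on tiny instances", {
  coords <- cbind(c(0, 0.5, 4, 5), c(1, 0, 2, 3))
  groups <- c("a", "a", "b", "b")
  stat <- function(g) {
    mx <- tapply(coords[, 1], g, mean); my <- tapply(coords[, 2], g, mean)
    sum(abs(mx - my))
  }
  observed <- stat(groups)
  # enumerate all distinct label assignments (2 of 4 positions are "a")
  combos <- combn(4, 2)
  exact_ge <- mean(apply(combos, 2, function(ix) {
    g <- rep("b", 4); g[ix] <- "a"; stat(g) >= observed - 1e-12
  }))
  res <- trajectory_permutation_test(coords, groups, n_perm = 4000, seed = 90)
  expect_equal(res$observed, observed)
  expect_equal(res$p_value, exact_ge, tolerance = 0.05)
})

test_that("fully separated groups attain the add-one lower bound", {
  # the cross-axis statistic is maximal when the groups sit on opposite
  # sides of the x = y diagonal, so separate them across it
  set.seed(91)
  g1 <- cbind(rnorm(10, 0, 0.05), rnorm(10, 100, 0.05))
  g2 <- cbind(rnorm(10, 100, 0.05), rnorm(10, 0, 0.05))
  res <- trajectory_permutation_test(rbind(g1, g2), rep(c("a", "b"), each = 10),
                                     n_perm = 1000, seed = 92)
  expect_equal(res$p_value, 1 / 1001)
  # the centroid-distance variant detects a plain one-axis offset too
  g3 <- cbind(rnorm(10, 100, 0.05), rnorm(10, 0, 0.05))
  g4 <- cbind(rnorm(10, 0, 0.05), rnorm(10, 0, 0.05))
  res2 <- trajectory_permutation_test(rbind(g3, g4), rep(c("a", "b"), each = 10),
                                      n_perm = 1000, statistic = "centroid",
                                      seed = 92)
  expect_equal(res2$p_value, 1 / 1001)
})

test_that("null data produce uniform-ish p-values, and bounds always hold", {
  ps <- sapply(1:20, function(i) {
    set.seed(100 + i)
    coords <- cbind(rnorm(30), rnorm(30))
    trajectory_permutation_test(coords, rep(c("a", "b"), 15),
                                n_perm = 200, seed = i)$p_value
  })
  expect_gte(median(ps), 0.2)
  expect_lte(median(ps), 0.8)
  expect_true(all(ps >= 1 / 201 & ps <= 1))
})

test_that("the statistic is invariant to translation of all coordinates", {
  set.seed(93)
  coords <- cbind(rnorm(20), rnorm(20))
  groups <- rep(c("a", "b"), each = 10)
  r1 <- trajectory_permutation_test(coords, groups, n_perm = 100, seed = 94)
  shifted <- coords + matrix(c(5, 5), 20, 2, byrow = TRUE)
  r2 <- trajectory_permutation_test(shifted, groups, n_perm = 100, seed = 94)
  expect_equal(r1$observed, r2$observed)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("input contracts are enforced", {
  coords <- cbind(1:4, 1:4)
  expect_error(trajectory_permutation_test(coords, rep("a", 4)), "two groups")
  expect_error(trajectory_permutation_test(coords, c("a", "a", "a", "b")),
               "at least 2 points")
  expect_error(trajectory_permutation_test(coords, rep(c("a", "b"), 2),
                                           n_perm = 0), "n_perm")
  expect_error(trajectory_permutation_test(cbind(1:4), rep(c("a", "b"), 2)),
               "two columns")
})

test_that("RT profiles write as bedGraph", {
  rt <- c(`chr1:0-100000` = 0.5, `chr1:100000-200000` = NA, `chr2:0-100000` = 1)
  f <- withr::local_tempfile(fileext = ".bedgraph")
  write_rt_bedgraph(rt, f)
  lines <- readLines(f)
  expect_match(lines[1], "bedGraph")
  expect_equal(length(lines), 3)  # header + 2 defined bins
})
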