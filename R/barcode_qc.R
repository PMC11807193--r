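# Barcode validation by read count.
#
# Demultiplexed sequencing barcodes split into a low-read (invalid) and a
# high-read (valid) population. After a hard floor removes the noise peak,
# the two populations are modelled as log-normal distributions D1 (lower)
# and D2 (upper) fitted by expectation-maximisation, and a read-count
# cutoff between them separates valid from invalid barcodes.

# Normalise input to a data.frame(barcode, reads).
as_barcode_table <- function(counts) {
  if (is.data.frame(counts)) {
    if (!all(c("barcode", "reads") %in% names(counts))) {
      stop("barcode table needs columns 'barcode' and 'reads'")
    }
    data.frame(barcode = as.character(counts$barcode),
               reads = as.numeric(counts$reads), stringsAsFactors = FALSE)
  } else {
    bc <- names(counts)
    if (is.null(bc)) bc <- sprintf("BC%05d", seq_along(counts))
    data.frame(barcode = bc, reads = as.numeric(counts), stringsAsFactors = FALSE)
  }
}

#' Remove barcodes below a hard read-count floor
#'
#' Barcodes with fewer than `min_reads` reads (default 30,000) are too
#' shallow to be informative and are removed before mixture fitting so
#' that only two read-count populations remain.
#'
#' @param counts numeric vector of per-barcode read counts (optionally
#'   named) or data.frame with columns `barcode`, `reads`.
#' @param min_reads floor below which barcodes are discarded.
#' @return data.frame (`barcode`, `reads`) of surviving barcodes.
#' @export
prefilter_counts <- function(counts, min_reads = 30000) {
  tab <- as_barcode_table(counts)
  if (nrow(tab) == 0) stop("empty barcode table")
  if (any(tab$reads < 0) || any(tab$reads != round(tab$reads))) {
    stop("read counts must be non-negative integers")
  }
  out <- tab[tab$reads >= min_reads, , drop = FALSE]
  if (nrow(out) == 0) stop("no barcodes survive the ", min_reads, "-read prefilter")
  rownames(out) <- NULL
  out
}

#' Fit a two-component log-normal mixture by expectation-maximisation
#'
#' Read counts are modelled as a mixture of two log-normal densities. The
#' E-step computes, for every barcode, the responsibility `gamma` of the
#' upper (valid) component as the ratio of the two densities evaluated at
#' its read count; the M-step re-estimates each component's log-scale
#' location and scale as `gamma`-weighted moments. Iteration stops when the
#' largest absolute change in `gamma` falls below `tol`.
#'
#' By default the responsibilities contain no mixing proportions (the two
#' components are weighted equally in the E-step); `weighted = TRUE`
#' switches to standard EM with estimated mixing proportions.
#'
#' @param counts read counts (vector or `barcode`/`reads` data.frame),
#'   typically after [prefilter_counts()].
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on `max |delta gamma|`.
#' @param weighted use mixing proportions in the E-step.
#' @return object of class `lognormal_mixture`: location/scale of the lower
#'   (`mu_d1`, `sigma_d1`) and upper (`mu_d2`, `sigma_d2`) components,
#'   per-barcode `gamma`, `n_iter`, `converged`, `bimodal` flag and the
#'   input table.
#' @export
fit_lognormal_mixture <- function(counts, max_iter = 500, tol = 1e-6,
                                  weighted = FALSE) {
  tab <- as_barcode_table(counts)
  x <- tab$reads
  if (any(x <= 0)) stop("read counts must be positive for log-normal fitting")
  lx <- log(x)
  if (length(unique(x)) < 2) stop("need at least 2 distinct positive counts")
  # Initialise each component from one half of the log-count distribution.
  med <- stats::median(lx)
  lo <- lx[lx <= med]; hi <- lx[lx > med]
  if (length(hi) == 0) { hi <- lo }
  mu1 <- mean(lo); s1 <- max(stats::sd(lo), 1e-3)
  mu2 <- mean(hi); s2 <- max(stats::sd(hi), 1e-3)
  if (is.na(s1)) s1 <- 1e-3
  if (is.na(s2)) s2 <- 1e-3
  pi2 <- 0.5
  gamma <- rep(0.5, length(x))
  converged <- FALSE
  delta_trace <- numeric(0)
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    f1 <- stats::dlnorm(x, mu1, s1)
    f2 <- stats::dlnorm(x, mu2, s2)
    if (weighted) { f1 <- (1 - pi2) * f1; f2 <- pi2 * f2 }
    denom <- f1 + f2
    g <- ifelse(denom > 0, f2 / denom, 0.5)
    delta <- max(abs(g - gamma))
    delta_trace <- c(delta_trace, delta)
    gamma <- g
    w2 <- gamma; w1 <- 1 - gamma
    if (sum(w1) < 1e-12 || sum(w2) < 1e-12) break  # one component emptied
    mu1 <- sum(w1 * lx) / sum(w1)
    s1 <- sqrt(sum(w1 * (lx - mu1)^2) / sum(w1))
    mu2 <- sum(w2 * lx) / sum(w2)
    s2 <- sqrt(sum(w2 * (lx - mu2)^2) / sum(w2))
    s1 <- max(s1, 1e-4); s2 <- max(s2, 1e-4)
    if (weighted) pi2 <- mean(gamma)
    if (delta < tol) { converged <- TRUE; break }
  }
  # Label components so that D1 is the lower read-count distribution.
  if (mu1 > mu2) {
    tmp <- c(mu1, s1); mu1 <- mu2; s1 <- s2; mu2 <- tmp[1]; s2 <- tmp[2]
    gamma <- 1 - gamma
    pi2 <- 1 - pi2
  }
  pooled <- sqrt((s1^2 + s2^2) / 2)
  bimodal <- abs(mu2 - mu1) >= pooled / 4
  if (!converged) {
    warning("EM did not converge within ", max_iter, " iterations (max |delta gamma| = ",
            signif(delta_trace[length(delta_trace)], 3), ")")
  }
  if (!bimodal) {
    warning("read counts look unimodal (|mu_D2 - mu_D1| < pooled sigma / 4); ",
            "cutoff-based filtering is not meaningful")
  }
  structure(list(mu_d1 = mu1, sigma_d1 = s1, mu_d2 = mu2, sigma_d2 = s2,
                 gamma = gamma, pi_valid = if (weighted) pi2 else NA_real_,
                 weighted = weighted, n_iter = iter, converged = converged,
                 bimodal = bimodal, delta_trace = delta_trace, table = tab),
            class = "lognormal_mixture")
}

#' @export
print.lognormal_mixture <- function(x, ...) {
  cat("Two-component log-normal mixture fit\n")
  cat(sprintf("  D1 (invalid): mu = %.4f, sigma = %.4f (median %.0f reads)\n",
              x$mu_d1, x$sigma_d1, exp(x$mu_d1)))
  cat(sprintf("  D2 (valid):   mu = %.4f, sigma = %.4f (median %.0f reads)\n",
              x$mu_d2, x$sigma_d2, exp(x$mu_d2)))
  cat(sprintf("  %d barcodes, %d iterations, converged: %s, bimodal: %s\n",
              nrow(x$table), x$n_iter, x$converged, x$bimodal))
  invisible(x)
}

#' Read-count cutoff between the two mixture components
#'
#' `mode = "posterior"`: the smallest integer read count, between the two
#' component modes, at which the probability of belonging to the upper
#' component crosses 0.5 (the density crossing). `mode = "type1"`: the
#' count beyond which the upper-tail probability of the lower component D1
#' equals `alpha` (D1 is treated as the Type-I error distribution), i.e.
#' `exp(mu_D1 + sigma_D1 * z[1 - alpha])`.
#'
#' The returned cutoff is never below the `min_reads` prefilter floor.
#'
#' @param fit a [fit_lognormal_mixture()] result.
#' @param mode cutoff rule.
#' @param alpha Type-I error rate for `mode = "type1"`.
#' @param min_reads prefilter floor to compose with.
#' @return read-count threshold; barcodes at or above it are valid.
#' @export
find_cutoff <- function(fit, mode = c("posterior", "type1"), alpha = 0.05,
                        min_reads = 30000) {
  mode <- match.arg(mode)
  stopifnot(inherits(fit, "lognormal_mixture"))
  if (fit$mu_d1 >= fit$mu_d2) stop("components are not ordered (mu_D1 >= mu_D2)")
  if (mode == "type1") {
    cut <- exp(fit$mu_d1 + fit$sigma_d1 * stats::qnorm(1 - alpha))
  } else {
    mode1 <- exp(fit$mu_d1 - fit$sigma_d1^2)
    mode2 <- exp(fit$mu_d2 - fit$sigma_d2^2)
    h <- function(x) {
      stats::dlnorm(x, fit$mu_d2, fit$sigma_d2) - stats::dlnorm(x, fit$mu_d1, fit$sigma_d1)
    }
    if (h(mode1) >= 0 || h(mode2) <= 0) {
      stop("components too overlapped: no density crossing between the modes")
    }
    root <- stats::uniroot(h, c(mode1, mode2), tol = 1e-6)$root
    # smallest integer count with upper-component probability >= 0.5
    cut <- floor(root)
    while (h(cut) < 0) cut <- cut + 1
  }
  max(cut, min_reads)
}

#' Validate barcodes end to end
#'
#' Prefilter, mixture fit and cutoff in one call. If the surviving counts
#' are not bimodal, all of them are accepted (with a warning) and the
#' cutoff equals the prefilter floor.
#'
#' @param counts per-barcode read counts (vector or data.frame).
#' @param min_reads prefilter floor.
#' @param mode,alpha cutoff rule, see [find_cutoff()].
#' @param weighted see [fit_lognormal_mixture()].
#' @return list with `table` (data.frame `barcode`, `reads`, `gamma`,
#'   `valid`), `fit` and `cutoff`.
#' @export
classify_barcodes <- function(counts, min_reads = 30000,
                              mode = c("posterior", "type1"), alpha = 0.05,
                              weighted = FALSE) {
  mode <- match.arg(mode)
  kept <- prefilter_counts(counts, min_reads)
  fit <- fit_lognormal_mixture(kept, weighted = weighted)
  if (fit$bimodal) {
    cutoff <- find_cutoff(fit, mode = mode, alpha = alpha, min_reads = min_reads)
  } else {
    cutoff <- min_reads
  }
  tab <- data.frame(kept, gamma = fit$gamma, valid = kept$reads >= cutoff,
                    stringsAsFactors = FALSE)
  list(table = tab, fit = fit, cutoff = cutoff)
}
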