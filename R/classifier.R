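# Replication-state classification.
#
# A cell in S phase has partially duplicated its genome: copy numbers in
# early-replicating regions are doubled relative to its karyotype. A small
# feed-forward network (input -> 64 -> 32 -> 16 -> 1, rectified hidden
# units, sigmoid output) maps a complete autosomal copy-number profile to
# the probability that the cell is replicating. Training uses binary
# cross-entropy, the adam optimiser and early stopping (patience 15) on a
# validation carve-out; the training side is augmented with noisy profile
# duplicates so that noisy non-replicating cells are not mistaken for
# replicating ones.

# ---- minimal MLP -----------------------------------------------------------

mlp_init <- function(d_in, widths = c(64, 32, 16, 1)) {
  sizes <- c(d_in, widths)
  params <- list()
  for (l in seq_along(widths)) {
    fan_in <- sizes[l]
    params[[paste0("W", l)]] <- matrix(stats::rnorm(fan_in * sizes[l + 1],
                                                    sd = sqrt(2 / fan_in)),
                                       fan_in, sizes[l + 1])
    params[[paste0("b", l)]] <- rep(0, sizes[l + 1])
  }
  params
}

mlp_forward <- function(params, X) {
  L <- length(params) / 2
  act <- vector("list", L + 1)
  act[[1]] <- X
  for (l in seq_len(L)) {
    Z <- sweep(act[[l]] %*% params[[paste0("W", l)]], 2,
               params[[paste0("b", l)]], "+")
    act[[l + 1]] <- if (l < L) pmax(Z, 0) else 1 / (1 + exp(-Z))
  }
  act
}

mlp_gradients <- function(params, act, y) {
  L <- length(params) / 2
  n <- nrow(act[[1]])
  grads <- list()
  # sigmoid + BCE: delta at the output is (p - y) / n
  delta <- (act[[L + 1]] - y) / n
  for (l in rev(seq_len(L))) {
    grads[[paste0("W", l)]] <- crossprod(act[[l]], delta)
    grads[[paste0("b", l)]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(params[[paste0("W", l)]])) * (act[[l]] > 0)
    }
  }
  grads
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

mlp_predict <- function(params, X) {
  act <- mlp_forward(params, X)
  as.vector(act[[length(act)]])
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Normalise label input to logical "replicating".
as_replicating <- function(labels) {
  if (is.logical(labels)) return(labels)
  lab <- toupper(as.character(labels))
  out <- lab %in% c("S", "REPLICATING", "TRUE", "1")
  bad <- !out & !(lab %in% c("G1", "G2", "NON-REPLICATING", "NONREPLICATING", "FALSE", "0"))
  if (any(bad)) stop("unrecognised phase label(s): ", paste(unique(lab[bad]), collapse = ", "))
  out
}

# ---- training-set assembly -------------------------------------------------

#' Augment a training set with noisy profile duplicates
#'
#' Duplicates a random `dup_fraction` of the cells; each duplicate has a
#' noise fraction `q ~ Uniform(noise_span)` of its bins altered by +/-1
#' (equal sign probability, clipped at 0). Duplicates keep their original
#' label.
#'
#' @param x complete cells x bins feature matrix.
#' @param labels per-cell phase labels (logical replicating, or "S"/"G1").
#' @param dup_fraction fraction of cells to duplicate.
#' @param noise_span interval within \[0, 1\] for the per-duplicate noise
#'   fraction.
#' @param seed optional integer seed.
#' @return list with augmented `x` and `labels` (logical replicating).
#' @export
augment_training <- function(x, labels, dup_fraction = 0.5,
                             noise_span = c(0.05, 0.75), seed = NULL) {
  if (nrow(x) == 0) stop("empty training set")
  y <- as_replicating(labels)
  if (any(noise_span < 0) || any(noise_span > 1)) {
    stop("'noise_span' must lie within [0, 1]")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  n_dup <- round(dup_fraction * nrow(x))
  if (n_dup == 0) return(list(x = x, labels = y))
  pick <- sample.int(nrow(x), n_dup)
  dup <- x[pick, , drop = FALSE]
  for (i in seq_len(n_dup)) {
    q <- stats::runif(1, noise_span[1], noise_span[2])
    n_alter <- round(q * ncol(x))
    if (n_alter > 0) {
      pos <- sample.int(ncol(x), n_alter)
      dup[i, pos] <- pmax(dup[i, pos] + sample(c(-1, 1), n_alter, replace = TRUE), 0)
    }
  }
  rownames(dup) <- paste0(rownames(x)[pick], "_aug", seq_len(n_dup))
  list(x = rbind(x, dup), labels = c(y, y[pick]))
}

# Stratified index split: returns indices of the first part.
stratified_split <- function(y, prop) {
  take <- integer(0)
  for (cls in unique(y)) {
    idx <- which(y == cls)
    take <- c(take, sample(idx, round(prop * length(idx))))
  }
  sort(take)
}

#' Train the replication-state classifier
#'
#' Splits cells 80:20 into training and held-out test sets (stratified by
#' label, before augmentation), augments the training side with
#' [augment_training()], carves a stratified validation fraction out of the
#' augmented training data for early stopping, and trains the network with
#' binary cross-entropy and adam. Training stops when the validation loss
#' has not improved for `patience` epochs; the best-validation weights are
#' kept.
#'
#' @param x complete cells x bins copy-number matrix. Columns on sex
#'   chromosomes and columns containing any missing value are dropped.
#' @param labels per-cell phase labels (logical replicating, or "S"/"G1").
#' @param split training proportion of the 80:20 split.
#' @param augment apply data augmentation to the training side.
#' @param dup_fraction,noise_span augmentation parameters.
#' @param val_fraction validation carve-out of the augmented training side.
#' @param patience early-stopping patience in epochs.
#' @param max_epochs epoch cap.
#' @param batch_size minibatch size.
#' @param lr adam learning rate.
#' @param seed optional integer seed (weights, splits, augmentation,
#'   shuffling).
#' @return object of class `mnm_model`: network weights, the exact ordered
#'   `regions` the model expects, `test_accuracy` on the held-out 20%, and
#'   training metadata.
#' @export
train_classifier <- function(x, labels, split = 0.8, augment = TRUE,
                             dup_fraction = 0.5, noise_span = c(0.05, 0.75),
                             val_fraction = 0.1, patience = 15,
                             max_epochs = 300, batch_size = 32, lr = 1e-3,
                             seed = NULL) {
  validate_cn_matrix(x)
  y <- as_replicating(labels)
  if (length(y) != nrow(x)) stop("one label per cell required")
  if (length(unique(y)) < 2) stop("training data contain a single class")
  if (!is.null(seed)) withr::local_seed(seed)
  # autosomal, fully observed columns only
  keep <- intersect(autosomal_columns(x), which(colSums(is.na(x)) == 0))
  if (length(keep) == 0) stop("no complete autosomal bins available")
  x <- x[, keep, drop = FALSE]
  regions <- colnames(x)

  tr_idx <- stratified_split(y, split)
  te_idx <- setdiff(seq_len(nrow(x)), tr_idx)
  x_tr <- x[tr_idx, , drop = FALSE]; y_tr <- y[tr_idx]
  x_te <- x[te_idx, , drop = FALSE]; y_te <- y[te_idx]
  if (augment) {
    aug <- augment_training(x_tr, y_tr, dup_fraction, noise_span)
    x_tr <- aug$x; y_tr <- aug$labels
  }
  val_idx <- stratified_split(y_tr, val_fraction)
  x_val <- x_tr[val_idx, , drop = FALSE]; y_val <- y_tr[val_idx]
  x_fit <- x_tr[-val_idx, , drop = FALSE]; y_fit <- y_tr[-val_idx]

  params <- mlp_init(ncol(x))
  state <- list(t = 0,
                m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  best <- list(loss = Inf, params = params, epoch = 0)
  wait <- 0
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  n_fit <- nrow(x_fit)
  for (epoch in seq_len(max_epochs)) {
    ord <- sample.int(n_fit)
    starts <- seq(1, n_fit, by = batch_size)
    ep_loss <- 0
    for (s in starts) {
      b <- ord[s:min(s + batch_size - 1, n_fit)]
      act <- mlp_forward(params, x_fit[b, , drop = FALSE])
      ep_loss <- ep_loss + bce_loss(act[[length(act)]], y_fit[b]) * length(b)
      grads <- mlp_gradients(params, act, y_fit[b])
      upd <- adam_step(params, grads, state, lr = lr)
      params <- upd$params; state <- upd$state
    }
    val_loss <- bce_loss(mlp_predict(params, x_val), y_val)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = ep_loss / n_fit,
                                         val_loss = val_loss))
    if (val_loss < best$loss - 1e-8) {
      best <- list(loss = val_loss, params = params, epoch = epoch)
      wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= patience) break
    }
  }
  params <- best$params
  test_p <- mlp_predict(params, x_te)
  test_acc <- 100 * mean((test_p >= 0.5) == y_te)
  structure(list(weights = params, regions = regions,
                 widths = c(64, 32, 16, 1), threshold = 0.5,
                 test_accuracy = test_acc,
                 epochs_run = nrow(history), best_epoch = best$epoch,
                 val_loss = best$loss, history = history,
                 n_train = n_fit, n_test = length(te_idx)),
            class = "mnm_model")
}

#' @export
print.mnm_model <- function(x, ...) {
  cat(sprintf("Replication-state classifier: %d regions -> %s\n",
              length(x$regions), paste(x$widths, collapse = " -> ")))
  cat(sprintf("  trained %d epochs (best %d), held-out accuracy %.2f%% (n = %d)\n",
              x$epochs_run, x$best_epoch, x$test_accuracy, x$n_test))
  invisible(x)
}

# ---- prediction ------------------------------------------------------------

# Align a matrix to the model's region list. Regions absent from the input
# (or missing in a given cell) are filled per cell by linear interpolation
# between the nearest observed flanking bins on the same chromosome, with
# one-sided extension at chromosome ends. A chromosome with no observed
# data falls back to the cell's median copy number.
align_to_regions <- function(m, regions) {
  shared <- intersect(regions, colnames(m))
  if (length(shared) == 0) stop("no overlap between input bins and the model's region list")
  out <- matrix(NA_real_, nrow = nrow(m), ncol = length(regions),
                dimnames = list(rownames(m), regions))
  out[, shared] <- m[, shared, drop = FALSE]
  if (!anyNA(out)) return(out)
  bins <- parse_regions(regions)
  mid <- (bins$start + bins$end) / 2
  fallback_used <- FALSE
  for (chr in unique(bins$chrom)) {
    cols <- which(bins$chrom == chr)
    sub <- out[, cols, drop = FALSE]
    if (!anyNA(sub)) next
    xs <- mid[cols]
    for (i in seq_len(nrow(sub))) {
      obs <- which(!is.na(sub[i, ]))
      nas <- which(is.na(sub[i, ]))
      if (length(nas) == 0) next
      if (length(obs) == 0) {
        sub[i, nas] <- stats::median(m[i, ], na.rm = TRUE)
        fallback_used <- TRUE
      } else if (length(obs) == 1) {
        sub[i, nas] <- sub[i, obs]
      } else {
        sub[i, nas] <- stats::approx(xs[obs], sub[i, obs], xout = xs[nas],
                                     rule = 2)$y
      }
    }
    out[, cols] <- sub
  }
  if (fallback_used) {
    warning("chromosome(s) with no observed data: filled with per-cell medians")
  }
  out
}

#' Predict replication states
#'
#' Aligns the input matrix to the model's region list (absent regions are
#' reconstructed per cell by linear interpolation along the chromosome)
#' and returns a probability and a binary label for every cell.
#'
#' @param model an `mnm_model` from [train_classifier()] or [load_model()].
#' @param m copy-number matrix re-binned to the model's bin size.
#' @return data.frame with columns `cell`, `probability`, `replicating`,
#'   `phase` ("S"/"G1").
#' @export
predict_states <- function(model, m) {
  stopifnot(inherits(model, "mnm_model"))
  feats <- align_to_regions(m, model$regions)
  p <- mlp_predict(model$weights, feats)
  repl <- p >= model$threshold
  data.frame(cell = rownames(m), probability = p, replicating = repl,
             phase = ifelse(repl, "S", "G1"), stringsAsFactors = FALSE)
}

#' Discordance between external phase labels and model predictions
#'
#' Audit harness comparing an external (for instance FACS-derived) phase
#' column with the classifier's calls.
#'
#' @param model an `mnm_model`.
#' @param m copy-number matrix.
#' @param external per-cell external phase labels, in `m`'s row order.
#' @return list with per-cell `table` and `discordance` (percentage).
#' @export
audit_misclassification <- function(model, m, external) {
  ext <- as_replicating(external)
  pred <- predict_states(model, m)
  disagree <- pred$replicating != ext
  list(table = data.frame(pred, external_replicating = ext,
                          discordant = disagree),
       discordance = 100 * mean(disagree))
}

# ---- model persistence -----------------------------------------------------

#' Save a trained classifier as portable JSON
#'
#' @param model an `mnm_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "mnm_model"))
  payload <- list(
    format = "mnm_model",
    version = 1L,
    widths = model$widths,
    threshold = model$threshold,
    regions = model$regions,
    test_accuracy = model$test_accuracy,
    epochs_run = model$epochs_run,
    best_epoch = model$best_epoch,
    weights = lapply(model$weights, function(w) {
      if (is.matrix(w)) list(nrow = nrow(w), ncol = ncol(w), data = as.vector(w))
      else list(nrow = NA, ncol = NA, data = as.vector(w))
    }))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a classifier saved by [save_model()]
#'
#' @param path JSON model file.
#' @return an `mnm_model`.
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "mnm_model")) stop("not an mnm model file")
  weights <- lapply(payload$weights, function(w) {
    if (!is.null(w$nrow) && !is.na(w$nrow)) {
      matrix(as.numeric(unlist(w$data)), w$nrow, w$ncol)
    } else {
      as.numeric(unlist(w$data))
    }
  })
  structure(list(weights = weights, regions = payload$regions,
                 widths = payload$widths, threshold = payload$threshold,
                 test_accuracy = payload$test_accuracy,
                 epochs_run = payload$epochs_run,
                 best_epoch = payload$best_epoch),
            class = "mnm_model")
}
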