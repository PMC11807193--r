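# Reading, writing and re-binning single-cell copy-number tables.

#' Read single-cell copy numbers
#'
#' Two layouts are accepted. `"bed"`: a headerless tab-separated table with
#' columns chromosome, start, end, copy number, cell identifier (lines
#' starting with `#` are ignored). `"matrix"`: a tab- or comma-separated
#' table whose first column holds cell identifiers and whose remaining
#' column headers are `"chr:start-end"` region strings.
#'
#' Cells absent from a region, and copy-number fields that do not parse as
#' numbers, become missing values (`NA`).
#'
#' @param path input file.
#' @param layout `"bed"` or `"matrix"`.
#' @return numeric matrix, cells x bins, with `"chr:start-end"` colnames.
#' @export
read_cn <- function(path, layout = c("bed", "matrix")) {
  layout <- match.arg(layout)
  if (layout == "bed") {
    tab <- data.table::fread(path, header = FALSE, sep = "\t", data.table = FALSE)
    if (ncol(tab) < 5) stop("BED layout needs 5 columns: chrom, start, end, copy_number, cell_id")
    names(tab)[1:5] <- c("chrom", "start", "end", "cn", "cell")
    tab$cn <- suppressWarnings(as.numeric(tab$cn))
    bins <- unique(data.frame(chrom = as.character(tab$chrom),
                              start = as.numeric(tab$start),
                              end = as.numeric(tab$end)))
    bins <- sort_bins(bins)
    regions <- region_names(bins)
    cells <- unique(as.character(tab$cell))
    m <- matrix(NA_real_, nrow = length(cells), ncol = length(regions),
                dimnames = list(cells, regions))
    ri <- match(as.character(tab$cell), cells)
    ci <- match(region_names(data.frame(chrom = tab$chrom, start = tab$start,
                                        end = tab$end)), regions)
    idx <- cbind(ri, ci)
    key <- paste(ri, ci)
    if (anyDuplicated(key)) {
      n_vals <- vapply(split(tab$cn, key),
                       function(v) length(unique(v[!is.na(v)])), 1L)
      if (any(n_vals > 1)) {
        bad <- names(n_vals)[n_vals > 1][1]
        i <- match(bad, key)
        stop("conflicting duplicate records for (cell, region): ",
             tab$cell[i], " ", regions[ci[i]])
      }
      keep <- !duplicated(key)
      m[idx[keep, , drop = FALSE]] <- tab$cn[keep]
    } else {
      m[idx] <- tab$cn
    }
    m
  } else {
    tab <- data.table::fread(path, header = TRUE, data.table = FALSE)
    cells <- as.character(tab[[1]])
    if (anyDuplicated(cells)) stop("duplicate cell identifiers in matrix layout")
    vals <- tab[, -1, drop = FALSE]
    regions <- colnames(vals)
    bins <- parse_regions(regions)
    m <- matrix(NA_real_, nrow = length(cells), ncol = length(regions),
                dimnames = list(cells, regions))
    for (j in seq_along(regions)) {
      m[, j] <- suppressWarnings(as.numeric(vals[[j]]))
    }
    bins_sorted <- sort_bins(bins)
    m[, match(region_names(bins_sorted), regions), drop = FALSE]
  }
}

#' Write single-cell copy numbers
#'
#' Inverse of [read_cn()]. In BED layout missing values are omitted (a cell
#' simply has no record for that region); in matrix layout they are written
#' as `NA`.
#'
#' @param m copy-number matrix.
#' @param path output file.
#' @param layout `"bed"` or `"matrix"`.
#' @return `path`, invisibly.
#' @export
write_cn <- function(m, path, layout = c("bed", "matrix")) {
  layout <- match.arg(layout)
  validate_cn_matrix(m)
  if (layout == "bed") {
    bins <- bin_index(m)
    long <- data.frame(
      chrom = rep(bins$chrom, each = nrow(m)),
      start = rep(bins$start, each = nrow(m)),
      end = rep(bins$end, each = nrow(m)),
      cn = as.vector(m),
      cell = rep(rownames(m), ncol(m)))
    long <- long[!is.na(long$cn), , drop = FALSE]
    data.table::fwrite(long, path, sep = "\t", col.names = FALSE)
  } else {
    out <- data.frame(cell_id = rownames(m), m, check.names = FALSE)
    data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  }
  invisible(path)
}

#' Rearrange copy numbers into fixed genomic windows
#'
#' Re-bins each cell independently into `bin_size` non-overlapping windows
#' tiling every chromosome of `chrom_sizes`. The value of an output window
#' is the median of the input values whose bins overlap the window by at
#' least 50% of the input bin's length (an input bin split exactly 50/50
#' contributes to both windows). Windows with no qualifying input are
#' missing.
#'
#' @param m copy-number matrix.
#' @param bin_size output window width in bases.
#' @param chrom_sizes chromosome sizes (data.frame `chrom`,`size` or file
#'   path); must cover every chromosome present in `m`.
#' @return re-binned copy-number matrix.
#' @export
rebin <- function(m, bin_size = 1e5, chrom_sizes = NULL) {
  validate_cn_matrix(m)
  if (bin_size <= 0) stop("'bin_size' must be positive")
  if (is.null(chrom_sizes)) stop("'chrom_sizes' is required")
  if (is.character(chrom_sizes)) chrom_sizes <- read_chrom_sizes(chrom_sizes)
  bins <- bin_index(m)
  missing_chr <- setdiff(unique(bins$chrom), chrom_sizes$chrom)
  if (length(missing_chr)) {
    stop("chromosome(s) absent from chrom_sizes: ", paste(missing_chr, collapse = ", "))
  }
  out_bins <- make_bins(chrom_sizes, bin_size)
  regions_out <- region_names(out_bins)
  # Map each input bin to the output windows it overlaps by >= 50% of its
  # own length. An input bin can span at most a handful of windows.
  first_w <- floor(bins$start / bin_size)
  last_w <- floor((bins$end - 1) / bin_size)
  reps <- as.integer(last_w - first_w + 1)
  src <- rep(seq_len(nrow(bins)), reps)
  w <- unlist(lapply(seq_len(nrow(bins)), function(i) first_w[i]:last_w[i]))
  ov <- pmin(bins$end[src], (w + 1) * bin_size) - pmax(bins$start[src], w * bin_size)
  keep <- ov >= 0.5 * (bins$end[src] - bins$start[src])
  src <- src[keep]; w <- w[keep]
  target <- match(region_names(data.frame(chrom = bins$chrom[src],
                                          start = w * bin_size,
                                          end = pmin((w + 1) * bin_size,
                                                     chrom_sizes$size[match(bins$chrom[src], chrom_sizes$chrom)]))),
                  regions_out)
  src <- src[!is.na(target)]; target <- target[!is.na(target)]
  out <- matrix(NA_real_, nrow = nrow(m), ncol = length(regions_out),
                dimnames = list(rownames(m), regions_out))
  by_target <- split(src, target)
  for (tg in names(by_target)) {
    cols <- by_target[[tg]]
    sub <- m[, cols, drop = FALSE]
    out[, as.integer(tg)] <- apply(sub, 1, stats::median, na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  out
}

#' Temporarily remove bins with no data
#'
#' Drops matrix columns in which every cell is missing, recording them so
#' that [restore_empty_bins()] can reinsert them (as missing) after
#' processing.
#'
#' @param m copy-number matrix.
#' @return list with `matrix` (columns removed) and `removed` (data.frame
#'   of original column `index` and `region`).
#' @export
drop_empty_bins <- function(m) {
  empty <- which(colSums(!is.na(m)) == 0)
  removed <- data.frame(index = as.integer(empty),
                        region = colnames(m)[empty],
                        stringsAsFactors = FALSE)
  list(matrix = m[, setdiff(seq_len(ncol(m)), empty), drop = FALSE],
       removed = removed)
}

#' Reinsert bins removed by [drop_empty_bins()]
#'
#' @param m processed matrix (without the removed columns).
#' @param removed the `removed` data.frame from [drop_empty_bins()].
#' @return matrix with the removed bins reinserted as all-missing columns,
#'   in their original positions.
#' @export
restore_empty_bins <- function(m, removed) {
  if (nrow(removed) == 0) return(m)
  total <- ncol(m) + nrow(removed)
  out <- matrix(NA_real_, nrow = nrow(m), ncol = total)
  rownames(out) <- rownames(m)
  cn <- character(total)
  kept <- setdiff(seq_len(total), removed$index)
  out[, kept] <- m
  cn[kept] <- colnames(m)
  cn[removed$index] <- removed$region
  colnames(out) <- cn
  out
}
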