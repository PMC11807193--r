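# Genomic bin bookkeeping.
#
# Copy-number matrices in this package are plain numeric matrices with one
# row per cell (rownames = cell identifiers) and one column per genomic bin
# (colnames = "chr:start-end" region strings, 0-based half-open, BED
# convention). A "bin index" is the parsed form: a data.frame with columns
# chrom, start, end, sorted by (chrom, start) and non-overlapping.

#' Tile chromosomes into fixed-width genomic bins
#'
#' Builds the ordered bin index that tiles every chromosome in
#' `chrom_sizes` with non-overlapping windows of `bin_size` bases. The last
#' window of a chromosome is truncated at the chromosome end and may be
#' shorter than `bin_size`.
#'
#' @param chrom_sizes data.frame with columns `chrom` and `size` (bases), or
#'   the path of a two-column tab-separated file in that layout.
#' @param bin_size window width in bases (default 100 kb).
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open).
#' @export
#' @examples
#' make_bins(data.frame(chrom = "chr1", size = 250000), bin_size = 1e5)
make_bins <- function(chrom_sizes, bin_size = 1e5) {
  if (is.character(chrom_sizes)) chrom_sizes <- read_chrom_sizes(chrom_sizes)
  stopifnot(is.data.frame(chrom_sizes), all(c("chrom", "size") %in% names(chrom_sizes)))
  if (bin_size <= 0) stop("'bin_size' must be a positive number of bases")
  pieces <- lapply(seq_len(nrow(chrom_sizes)), function(i) {
    size <- chrom_sizes$size[i]
    starts <- seq(0, size - 1, by = bin_size)
    data.frame(chrom = chrom_sizes$chrom[i], start = starts,
               end = pmin(starts + bin_size, size))
  })
  do.call(rbind, pieces)
}

#' Read a chromosome-sizes table
#'
#' @param path two-column tab-separated file: chromosome name, length in
#'   bases (no header).
#' @return data.frame with columns `chrom`, `size`.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("chromosome-sizes file must have two columns")
  data.frame(chrom = as.character(tab[[1]]), size = as.numeric(tab[[2]]))
}

#' Format a bin index as "chr:start-end" region strings
#'
#' @param bins bin index data.frame (`chrom`, `start`, `end`).
#' @return character vector of region strings.
#' @export
region_names <- function(bins) {
  sprintf("%s:%.0f-%.0f", bins$chrom, bins$start, bins$end)
}

#' Parse "chr:start-end" region strings into a bin index
#'
#' @param x character vector of region strings.
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
parse_regions <- function(x) {
  m <- regmatches(x, regexec("^(.+):([0-9]+)-([0-9]+)$", x))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("malformed region header(s): ", paste(utils::head(x[bad], 3), collapse = ", "))
  }
  out <- data.frame(chrom = vapply(m, `[`, "", 2L),
                    start = as.numeric(vapply(m, `[`, "", 3L)),
                    end = as.numeric(vapply(m, `[`, "", 4L)))
  if (any(out$end <= out$start)) stop("region with end <= start")
  out
}

#' Bin index of a copy-number matrix
#'
#' @param m copy-number matrix (cells x bins, "chr:start-end" colnames).
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
bin_index <- function(m) parse_regions(colnames(m))

#' Autosome test for chromosome names
#'
#' Sex (X, Y) and mitochondrial chromosomes are retained in matrices but
#' excluded from classifier and clustering feature spaces.
#'
#' @param chrom character vector of chromosome names.
#' @return logical vector.
#' @export
is_autosome <- function(chrom) {
  !grepl("^(chr)?(X|Y|M|MT)$", chrom, ignore.case = TRUE)
}

# Columns of `m` on autosomes.
autosomal_columns <- function(m) {
  which(is_autosome(bin_index(m)$chrom))
}

# Natural ordering for chromosome names: numeric part first, then X, Y, M.
chrom_order <- function(chrom) {
  stripped <- sub("^chr", "", chrom, ignore.case = TRUE)
  num <- suppressWarnings(as.numeric(stripped))
  special <- match(toupper(stripped), c("X", "Y", "M", "MT"))
  key <- ifelse(!is.na(num), num, 1e6 + ifelse(is.na(special), 99, special))
  order(key, chrom)
}

# Sort a bin data.frame by (chromosome, start) in natural order and check
# the non-overlap invariant.
sort_bins <- function(bins) {
  ord <- chrom_order(bins$chrom)
  bins <- bins[ord, , drop = FALSE]
  bins <- bins[order(match(bins$chrom, unique(bins$chrom)), bins$start), , drop = FALSE]
  rownames(bins) <- NULL
  by_chr <- split(bins, bins$chrom)
  for (b in by_chr) {
    if (nrow(b) > 1 && any(b$start[-1] < b$end[-nrow(b)])) {
      stop("overlapping bins on ", b$chrom[1])
    }
  }
  bins
}

# Validate a cells x bins matrix: named dimensions, parseable regions,
# non-negative or missing values.
validate_cn_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("copy-number data must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("copy-number matrix needs cell rownames and region colnames")
  }
  bin_index(m)
  if (any(m < 0, na.rm = TRUE)) stop("negative copy numbers are not allowed")
  invisible(m)
}
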