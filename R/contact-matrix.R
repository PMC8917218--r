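#' Construct a binned contact matrix
#'
#' A `contact_matrix` couples a bin table with a sparse upper-triangular
#' count store keyed by global bin index. Symmetry is implicit: only pairs
#' with `bin1 <= bin2` are stored; constructing with `bin1 > bin2` entries
#' folds them onto the upper triangle by summation, as are duplicate keys.
#'
#' @param bins bin table (see [make_bins()]); validated on construction.
#' @param counts `data.frame` with columns `bin1`, `bin2` (1-based global
#'   bin indices) and `count`.
#' @param balanced logical; `FALSE` for raw integer counts, `TRUE` for
#'   real-valued balanced entries.
#' @param bias optional per-bin multiplicative bias (set by [ice_balance()]).
#' @param mask logical per-bin exclusion mask (`TRUE` = excluded).
#' @return object of class `contact_matrix`.
#' @export
contact_matrix <- function(bins, counts, balanced = FALSE, bias = NULL,
                           mask = NULL) {
  bins <- validate_bins(bins)
  n <- nrow(bins)
  stopifnot(is.data.frame(counts),
            all(c("bin1", "bin2", "count") %in% names(counts)))
  if (nrow(counts) > 0) {
    if (any(counts$bin1 < 1 | counts$bin1 > n | counts$bin2 < 1 | counts$bin2 > n))
      stop("bin index out of range (matrix has ", n, " bins)")
    if (any(counts$count < 0)) stop("negative contact counts")
    if (!balanced && any(counts$count != round(counts$count)))
      stop("raw contact counts must be integers")
  }
  i <- pmin(counts$bin1, counts$bin2)
  j <- pmax(counts$bin1, counts$bin2)
  key <- (i - 1) * n + j
  agg <- rowsum(as.numeric(counts$count), key, reorder = TRUE)
  k <- as.numeric(rownames(agg))
  counts <- data.frame(bin1 = as.integer((k - 1) %/% n) + 1L,
                       bin2 = as.integer((k - 1) %% n) + 1L,
                       count = as.numeric(agg[, 1]))
  counts <- counts[counts$count != 0, , drop = FALSE]
  rownames(counts) <- NULL
  if (is.null(mask)) mask <- rep(FALSE, n)
  stopifnot(length(mask) == n)
  if (any(mask)) {
    drop <- mask[counts$bin1] | mask[counts$bin2]
    counts <- counts[!drop, , drop = FALSE]
  }
  structure(list(bins = bins, counts = counts,
                 binwidth = attr(bins, "binwidth"),
                 balanced = balanced, bias = bias, mask = mask),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %d bins (%d bp), %d stored pairs, %s%s\n",
              n_bins(x), x$binwidth, nrow(x$counts),
              if (x$balanced) "balanced" else "raw counts",
              if (any(x$mask)) sprintf(", %d bins masked", sum(x$mask)) else ""))
  invisible(x)
}

#' Number of bins in a contact matrix
#' @param cm a `contact_matrix`.
#' @export
n_bins <- function(cm) nrow(cm$bins)

chrom_of_bin <- function(cm) cm$bins$chrom

#' Per-bin marginal sums
#'
#' Sum of stored contact values touching each bin. The diagonal is excluded
#' by default, matching the balancing convention.
#'
#' @param cm a `contact_matrix`.
#' @param exclude_diag drop `(i,i)` entries from the sums.
#' @return numeric vector of length `n_bins(cm)`; `NA` for masked bins.
#' @export
marginals <- function(cm, exclude_diag = TRUE) {
  n <- n_bins(cm)
  m <- numeric(n)
  cnt <- cm$counts
  if (exclude_diag) cnt <- cnt[cnt$bin1 != cnt$bin2, , drop = FALSE]
  if (nrow(cnt) > 0) {
    off <- cnt$bin1 != cnt$bin2
    idx <- c(cnt$bin1, cnt$bin2[off])
    val <- c(cnt$count, cnt$count[off])
    s <- rowsum(val, idx)
    m[as.integer(rownames(s))] <- s[, 1]
  }
  m[cm$mask] <- NA_real_
  m
}

# Symmetric sparse matrix of stored values (both triangles), optionally
# with the diagonal zeroed. dgCMatrix, masked bins keep empty rows.
cm_sparse <- function(cm, drop_diag = FALSE) {
  n <- n_bins(cm)
  cnt <- cm$counts
  if (drop_diag) cnt <- cnt[cnt$bin1 != cnt$bin2, , drop = FALSE]
  off <- cnt$bin1 != cnt$bin2
  Matrix::sparseMatrix(i = c(cnt$bin1, cnt$bin2[off]),
                       j = c(cnt$bin2, cnt$bin1[off]),
                       x = c(cnt$count, cnt$count[off]),
                       dims = c(n, n))
}

# Dense symmetric matrix restricted to one chromosome (local indices);
# masked bins become NA rows/columns.
cm_dense_chrom <- function(cm, chrom) {
  sel <- which(cm$bins$chrom == chrom)
  n <- length(sel)
  lo <- min(sel); hi <- max(sel)
  d <- matrix(0, n, n)
  cnt <- cm$counts
  keep <- cnt$bin1 >= lo & cnt$bin2 <= hi & cnt$bin2 >= lo & cnt$bin1 <= hi
  cnt <- cnt[keep, , drop = FALSE]
  if (nrow(cnt) > 0) {
    i <- cnt$bin1 - lo + 1L; j <- cnt$bin2 - lo + 1L
    d[cbind(i, j)] <- cnt$count
    d[cbind(j, i)] <- cnt$count
  }
  msk <- cm$mask[sel]
  d[msk, ] <- NA_real_
  d[, msk] <- NA_real_
  d
}

#' Coarsen a contact matrix to a larger bin width
#'
#' Sums stored values over groups of consecutive bins within each
#' chromosome. GC content of a coarse bin is the mean over its constituent
#' fine bins; a coarse bin is masked only if all of its constituents are
#' masked. Works on raw or balanced matrices (values are summed either way).
#'
#' @param cm a `contact_matrix`.
#' @param target_binwidth new bin width; must be an integer multiple of the
#'   current one.
#' @return a `contact_matrix` at the coarser resolution (bias dropped).
#' @export
coarsen <- function(cm, target_binwidth) {
  bw <- cm$binwidth
  if (target_binwidth == bw) return(cm)
  if (target_binwidth %% bw != 0)
    stop("target bin width ", target_binwidth,
         " is not a multiple of the current bin width ", bw)
  chroms <- unique(cm$bins$chrom)
  chrom_lengths <- vapply(chroms, function(ch) max(cm$bins$end[cm$bins$chrom == ch]),
                          numeric(1))
  names(chrom_lengths) <- chroms
  coarse_bins <- make_bins(chrom_lengths, target_binwidth)
  # map each fine bin to its coarse bin
  mid <- cm$bins$start
  map <- bin_index(coarse_bins, cm$bins$chrom, mid)
  gc_new <- as.numeric(tapply(cm$bins$gc, map, mean))
  coarse_bins$gc <- NA_real_
  coarse_bins$gc[as.integer(names(tapply(cm$bins$gc, map, mean)))] <- gc_new
  mask_new <- as.logical(tapply(cm$mask, map, all))
  mask_full <- rep(TRUE, nrow(coarse_bins))
  mask_full[as.integer(names(tapply(cm$mask, map, all)))] <- mask_new
  cnt <- cm$counts
  contact_matrix(coarse_bins,
                 data.frame(bin1 = map[cnt$bin1], bin2 = map[cnt$bin2],
                            count = cnt$count),
                 balanced = cm$balanced, mask = mask_full)
}
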