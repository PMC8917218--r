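#' Build a uniform bin table over a genome
#'
#' Tiles each chromosome with fixed-width bins (the last bin of a chromosome
#' may be shorter). Bins carry a global, strictly increasing index implied by
#' row order: chromosomes in the order given, positions ascending.
#'
#' @param chrom_lengths named integer vector of chromosome lengths in bp.
#' @param binwidth bin width in bp.
#' @param gc optional per-bin GC fraction in `[0,1]` (recycled or full length);
#'   defaults to `NA`.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `gc`
#'   (0-based half-open coordinates) and attribute `binwidth`.
#' @export
make_bins <- function(chrom_lengths, binwidth, gc = NA_real_) {
  stopifnot(length(chrom_lengths) >= 1, !is.null(names(chrom_lengths)),
            binwidth >= 1)
  pieces <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0L, len - 1L, by = binwidth)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + binwidth, len),
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, pieces)
  bins$gc <- rep_len(gc, nrow(bins))
  rownames(bins) <- NULL
  attr(bins, "binwidth") <- as.integer(binwidth)
  bins
}

#' Validate a bin table
#'
#' Checks the tiling invariants: per chromosome, bins start at 0, are
#' contiguous (no gaps or overlaps), and all but the last bin have the
#' declared width.
#'
#' @param bins bin table as returned by [make_bins()] or [read_bin_table()].
#' @param binwidth declared bin width; inferred from the table if missing.
#' @return the bin table, invisibly, with a `binwidth` attribute set.
#' @export
validate_bins <- function(bins, binwidth = NULL) {
  stopifnot(is.data.frame(bins),
            all(c("chrom", "start", "end") %in% names(bins)))
  if (is.null(binwidth)) {
    binwidth <- attr(bins, "binwidth")
    if (is.null(binwidth)) binwidth <- max(bins$end - bins$start)
  }
  if (any(bins$end <= bins$start)) stop("bin table contains empty bins")
  for (ch in unique(bins$chrom)) {
    b <- bins[bins$chrom == ch, ]
    if (b$start[1] != 0) stop("bins on ", ch, " do not start at 0")
    if (nrow(b) > 1) {
      if (any(b$start[-1] != b$end[-nrow(b)]))
        stop("bins on ", ch, " are not contiguous")
      if (any(b$end[-nrow(b)] - b$start[-nrow(b)] != binwidth))
        stop("non-terminal bin on ", ch, " deviates from bin width ", binwidth)
    }
  }
  attr(bins, "binwidth") <- as.integer(binwidth)
  invisible(bins)
}

#' Map genomic positions to global bin indices
#'
#' @param bins bin table.
#' @param chrom,pos vectors of chromosome names and 0-based positions.
#' @return integer vector of 1-based global bin indices (`NA` if off-table).
#' @export
bin_index <- function(bins, chrom, pos) {
  binwidth <- attr(bins, "binwidth")
  if (is.null(binwidth)) binwidth <- max(bins$end - bins$start)
  offsets <- c(0L, cumsum(table(factor(bins$chrom, levels = unique(bins$chrom)))))
  names(offsets) <- c(unique(bins$chrom), "..end")
  chrom_len <- tapply(bins$end, factor(bins$chrom, levels = unique(bins$chrom)), max)
  idx <- rep(NA_integer_, length(chrom))
  known <- chrom %in% unique(bins$chrom)
  ok <- known & pos >= 0 & pos < chrom_len[chrom] & !is.na(pos)
  idx[ok] <- as.integer(offsets[chrom[ok]] + (pos[ok] %/% binwidth) + 1L)
  idx
}

bins_granges <- function(bins) {
  GenomicRanges::GRanges(bins$chrom,
                         IRanges::IRanges(start = bins$start + 1L, end = bins$end))
}

# GRanges from a 0-based half-open data.frame (chrom/start/end)
df_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}
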