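#' Stitch peaks into elements
#'
#' Peaks of one mark whose gap is at most `stitch_distance` are merged
#' transitively into stitched elements (the classic 12.5-kb ROSE stitching
#' by default). Aggregate signal is the sum of `signal x width` over
#' constituent peaks.
#'
#' @param peaks peak `data.frame` (`chrom`, `start`, `end`, `signal`).
#' @param stitch_distance maximum gap in bp (default 12500); a gap of
#'   exactly `stitch_distance` merges, one bp more does not.
#' @return `data.frame` of elements: `chrom`, `start`, `end`,
#'   `n_constituents`, `signal` (aggregate), `element`; the input peak order
#'   mapping is in attribute `constituent_of`.
#' @export
stitch <- function(peaks, stitch_distance = 12500) {
  if (stitch_distance < 0) stop("stitch distance must be non-negative")
  if (nrow(peaks) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_constituents = integer(),
                      signal = numeric(), element = integer()))
  ord <- order(peaks$chrom, peaks$start, peaks$end)
  p <- peaks[ord, , drop = FALSE]
  new_chrom <- c(TRUE, p$chrom[-1] != p$chrom[-nrow(p)])
  run_end <- cummax_by(p$end, new_chrom)
  gap <- p$start - c(-Inf, run_end[-nrow(p)])
  cluster <- cumsum(new_chrom | gap > stitch_distance)
  agg <- function(f, x) as.numeric(tapply(x, cluster, f))
  out <- data.frame(chrom = as.character(tapply(p$chrom, cluster, `[`, 1)),
                    start = agg(min, p$start), end = agg(max, p$end),
                    n_constituents = as.integer(tapply(cluster, cluster, length)),
                    signal = agg(sum, p$signal * (p$end - p$start)),
                    stringsAsFactors = FALSE)
  out$element <- seq_len(nrow(out))
  constituent_of <- integer(nrow(peaks))
  constituent_of[ord] <- cluster
  attr(out, "constituent_of") <- constituent_of
  rownames(out) <- NULL
  out
}

# running maximum restarting where `restart` is TRUE
cummax_by <- function(x, restart) {
  out <- x
  for (i in seq_along(x)[-1])
    if (!restart[i]) out[i] <- max(out[i - 1], x[i])
  out
}

#' Split stitched elements into super and typical by the ROSE cutoff
#'
#' Elements are sorted by ascending aggregate signal; rank and signal are
#' rescaled to the unit square and the cutoff is the signal of the point
#' where the discrete slope of the scaled curve first exceeds 1 (the
#' geometric "tangent" criterion behind super-enhancer hockey-stick plots).
#' Elements with signal strictly above the cutoff are super. With fewer
#' than 3 elements, or all-equal signals, nothing is super.
#'
#' @param stitched output of [stitch()].
#' @param mark optional mark name used to label classes: `H3K27ac` gives
#'   SE/TE, `H3K27me3` SuReR/TyReR, `H3K9me2` SuHeR/TyHeR; other marks get
#'   super/typical.
#' @return the elements with `rank` (1 = highest signal), `super`, `class`
#'   columns and a `cutoff_signal` attribute.
#' @export
rank_and_cut <- function(stitched, mark = NULL) {
  x <- stitched
  n <- nrow(x)
  x$rank <- rank(-x$signal, ties.method = "first")
  if (n < 3) {
    if (n > 0) warning("fewer than 3 stitched elements; all typical")
    x$super <- rep(FALSE, n)
    cutoff <- Inf
  } else if (max(x$signal) == min(x$signal)) {
    x$super <- rep(FALSE, n)
    cutoff <- Inf
  } else {
    ord <- order(x$signal)
    s <- x$signal[ord]
    xs <- (seq_len(n) - 1) / (n - 1)
    ys <- (s - s[1]) / (s[n] - s[1])
    slope <- diff(ys) / diff(xs)
    j <- which(slope > 1)[1]
    cutoff <- if (is.na(j)) Inf else s[j]
    x$super <- x$signal > cutoff
  }
  labels <- switch(mark %||% "",
                   H3K27ac = c("SE", "TE"),
                   H3K27me3 = c("SuReR", "TyReR"),
                   H3K9me2 = c("SuHeR", "TyHeR"),
                   c("super", "typical"))
  x$class <- ifelse(x$super, labels[1], labels[2])
  attr(x, "cutoff_signal") <- cutoff
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stitch, rank and classify peaks of one mark
#'
#' Convenience wrapper: [stitch()] then [rank_and_cut()].
#'
#' @inheritParams stitch
#' @param mark mark name (decides the class labels, see [rank_and_cut()]).
#' @return classified element `data.frame`.
#' @export
call_stitched_elements <- function(peaks, mark, stitch_distance = 12500) {
  rank_and_cut(stitch(peaks, stitch_distance), mark = mark)
}

#' Promoter regions around gene TSSs
#'
#' The promoter covers `flank` bp on either side of the transcription start
#' site (TSS = `start` on the plus strand, `end - 1` on the minus strand),
#' clipped at chromosome ends when lengths are supplied.
#'
#' @param genes gene `data.frame` with `chrom`, `start`, `end`, `strand`,
#'   `gene_id` (and optionally `tpm`).
#' @param flank promoter half-width in bp (default 2000).
#' @param chrom_lengths optional named vector for right-clipping.
#' @return `data.frame`: `chrom`, `start`, `end`, `gene_id`, `tss` (+ `tpm`
#'   when present).
#' @export
define_promoters <- function(genes, flank = 2000, chrom_lengths = NULL) {
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  start <- pmax(0L, tss - as.integer(flank))
  end <- ifelse(genes$strand == "+", tss + as.integer(flank),
                tss + as.integer(flank) + 1L)
  if (!is.null(chrom_lengths))
    end <- pmin(end, chrom_lengths[genes$chrom])
  out <- data.frame(chrom = genes$chrom, start = start, end = as.integer(end),
                    gene_id = genes$gene_id, tss = tss,
                    stringsAsFactors = FALSE)
  if ("tpm" %in% names(genes)) out$tpm <- genes$tpm
  out
}

#' Define enhancers as non-promoter H3K27ac elements
#'
#' Stitched H3K27ac elements with zero overlap with any promoter are
#' enhancers; their SE/TE class is inherited from [rank_and_cut()].
#' Elements touching a promoter by even one bp are excluded (they remain
#' available as active-promoter evidence).
#'
#' @param elements classified H3K27ac elements (from
#'   [call_stitched_elements()]).
#' @param promoters from [define_promoters()].
#' @return the enhancer subset of `elements`.
#' @export
define_enhancers <- function(elements, promoters) {
  if (nrow(elements) == 0) return(elements)
  if (nrow(promoters) == 0) return(elements)
  ov <- GenomicRanges::countOverlaps(df_granges(elements),
                                     df_granges(promoters))
  out <- elements[ov == 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overlap fraction between two super-silencer sets
#'
#' Fraction of SuReR elements overlapping at least one SuHeR element, and
#' vice versa.
#'
#' @param surer,suher element `data.frame`s.
#' @return `c(surer = , suher = )`.
#' @export
silencer_overlap_fraction <- function(surer, suher) {
  if (nrow(surer) == 0 || nrow(suher) == 0)
    return(c(surer = 0, suher = 0))
  g1 <- df_granges(surer); g2 <- df_granges(suher)
  c(surer = mean(GenomicRanges::countOverlaps(g1, g2) > 0),
    suher = mean(GenomicRanges::countOverlaps(g2, g1) > 0))
}
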