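#' Insulation score track
#'
#' For each bin `i` the raw insulation is the mean balanced contact over the
#' square of pairs `(u, v)` with `u` in `(i-w, i]` and `v` in `(i, i+w]`
#' (`w = window_bp / binwidth`), i.e. the contacts crossing the bin within
#' the window; masked pairs are skipped. The score is `log2(raw / mean raw)`
#' with the mean taken over the chromosome's defined bins, so a uniform
#' matrix scores 0 everywhere and multiplying the matrix by a scalar leaves
#' the score unchanged. The score is NA where the window does not fit
#' within the chromosome or more than half of the window square is masked.
#' Local minima of this track mark domain boundaries.
#'
#' @param cm balanced `contact_matrix` (typically 40-kb bins).
#' @param window_bp window size in bp; must be a multiple of the bin width
#'   and at least 2 bins (default 480 kb).
#' @return `data.frame` per bin: `chrom`, `start`, `end`, `bin`, `raw`,
#'   `score`, with attribute `window_bins`.
#' @export
insulation_score <- function(cm, window_bp = 480e3) {
  bw <- cm$binwidth
  if (window_bp %% bw != 0)
    stop("window_bp must be a multiple of the bin width (", bw, ")")
  w <- as.integer(window_bp / bw)
  if (w < 2) stop("insulation window must be at least 2 bins")
  out <- data.frame(chrom = cm$bins$chrom, start = cm$bins$start,
                    end = cm$bins$end, bin = seq_len(n_bins(cm)),
                    raw = NA_real_, score = NA_real_)
  for (ch in unique(cm$bins$chrom)) {
    sel <- which(cm$bins$chrom == ch)
    n <- length(sel)
    if (n < 2 * w) next
    d <- cm_dense_chrom(cm, ch)
    ok <- !is.na(d)
    dz <- d; dz[!ok] <- 0
    # 2D prefix sums for O(1) window-square sums
    S <- matrix(0, n + 1, n + 1)
    S[-1, -1] <- t(apply(apply(dz, 2, cumsum), 1, cumsum))
    K <- matrix(0, n + 1, n + 1)
    K[-1, -1] <- t(apply(apply(ok + 0, 2, cumsum), 1, cumsum))
    rect <- function(M, r1, r2, c1, c2)
      M[r2 + 1, c2 + 1] - M[r1, c2 + 1] - M[r2 + 1, c1] + M[r1, c1]
    msk <- cm$mask[sel]
    raw <- rep(NA_real_, n)
    for (i in w:(n - w)) {
      if (msk[i]) next
      r1 <- i - w + 1; r2 <- i; c1 <- i + 1; c2 <- i + w
      k <- rect(K, r1, r2, c1, c2)
      if (k < 0.5 * w * w) next
      raw[i] <- rect(S, r1, r2, c1, c2) / k
    }
    mu <- mean(raw, na.rm = TRUE)
    score <- ifelse(!is.na(raw) & raw > 0 & mu > 0, log2(raw / mu), NA_real_)
    out$raw[sel] <- raw
    out$score[sel] <- score
  }
  attr(out, "window_bins") <- w
  attr(out, "binwidth") <- bw
  out
}

# Delta vector of an insulation track: mean score over (i, i+delta] minus
# mean over (i-delta, i]; NA where either window has any undefined score.
insulation_delta <- function(track, delta_bins) {
  chroms <- unique(track$chrom)
  delta <- rep(NA_real_, nrow(track))
  for (ch in chroms) {
    sel <- which(track$chrom == ch)
    s <- track$score[sel]
    n <- length(s)
    cs <- cumsum(ifelse(is.na(s), 0, s))
    nas <- cumsum(is.na(s))
    wsum <- function(a, b) {  # sum s[a..b], NA if any NA or out of range
      if (a < 1 || b > n) return(NA_real_)
      if ((nas[b] - if (a > 1) nas[a - 1] else 0) > 0) return(NA_real_)
      cs[b] - if (a > 1) cs[a - 1] else 0
    }
    dd <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      right <- wsum(i + 1, i + delta_bins)
      left <- wsum(i - delta_bins + 1, i)
      if (!is.na(right) && !is.na(left))
        dd[i] <- right / delta_bins - left / delta_bins
    }
    delta[sel] <- dd
  }
  delta
}

# Boundary-strength functional at bin i: max of delta over (i, i+delta]
# minus min over (i-delta, i]. Large at insulation minima, near 0 elsewhere.
delta_strength <- function(delta, track, delta_bins) {
  n <- length(delta)
  vapply(seq_len(n), function(i) {
    ri <- (i + 1):(i + delta_bins); li <- (i - delta_bins + 1):i
    if (min(li) < 1 || max(ri) > n) return(NA_real_)
    if (track$chrom[min(li)] != track$chrom[max(ri)]) return(NA_real_)
    r <- delta[ri]; l <- delta[li]
    if (anyNA(r) || anyNA(l)) return(NA_real_)
    max(r) - min(l)
  }, numeric(1))
}

#' Call TAD boundaries from an insulation track
#'
#' Candidate boundaries sit at minus-to-plus zero crossings of the delta
#' vector (difference between the mean score just downstream and just
#' upstream); of the two bins flanking a crossing the one with the lower
#' insulation score is taken. Boundary strength is the range of the delta
#' vector around the boundary (max over the downstream delta window minus
#' min over the upstream window); boundaries weaker than `min_strength`
#' are dropped. Chromosome ends act as implicit boundaries for domain
#' construction but carry no strength and are not reported here.
#'
#' @param track insulation track from [insulation_score()].
#' @param delta_bp averaging window of the delta vector in bp (default
#'   120 kb; must be a multiple of the bin width).
#' @param min_strength minimum boundary strength in log2 units (default 0.1).
#' @return `data.frame`: `chrom`, `start`, `end` (the boundary bin), `bin`
#'   (global index), `strength`.
#' @export
call_boundaries <- function(track, delta_bp = 120e3, min_strength = 0.1) {
  bw <- attr(track, "binwidth")
  if (is.null(bw)) bw <- max(track$end - track$start)
  if (delta_bp %% bw != 0)
    stop("delta_bp must be a multiple of the bin width (", bw, ")")
  db <- as.integer(delta_bp / bw)
  delta <- insulation_delta(track, db)
  strength <- delta_strength(delta, track, db)
  res <- list()
  for (ch in unique(track$chrom)) {
    sel <- which(track$chrom == ch)
    dd <- delta[sel]
    n <- length(dd)
    for (i in seq_len(n - 1)) {
      if (is.na(dd[i]) || is.na(dd[i + 1])) next
      if (dd[i] < 0 && dd[i + 1] >= 0) {
        cand <- if (!is.na(track$score[sel[i + 1]]) &&
                    (is.na(track$score[sel[i]]) ||
                     track$score[sel[i + 1]] < track$score[sel[i]]))
          i + 1 else i
        st <- strength[sel[cand]]
        if (!is.na(st) && st >= min_strength)
          res[[length(res) + 1L]] <- data.frame(
            chrom = ch, start = track$start[sel[cand]],
            end = track$end[sel[cand]], bin = sel[cand], strength = st)
      }
    }
  }
  if (length(res) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), bin = integer(), strength = numeric()))
  out <- do.call(rbind, res)
  # a boundary spans one bin; collapse crossings that landed on the same bin
  out <- out[!duplicated(out$bin), ]
  rownames(out) <- NULL
  attr(out, "delta_bp") <- delta_bp
  out
}

#' Boundary-strength at arbitrary genomic positions
#'
#' Evaluates the same boundary-strength functional used by
#' [call_boundaries()] at each position (mapped to its bin), whether or not
#' the position is a called boundary, so insulation strength can be
#' compared across boundary sets, loop anchors, enhancers etc. Positions on
#' masked or edge regions give NA.
#'
#' @param track insulation track from [insulation_score()].
#' @param positions `data.frame` with `chrom` and `pos` (bp).
#' @param delta_bp delta window (must match the boundary call to be
#'   comparable).
#' @return numeric vector of strengths.
#' @export
insulation_at <- function(track, positions, delta_bp = 120e3) {
  bw <- attr(track, "binwidth")
  if (is.null(bw)) bw <- max(track$end - track$start)
  db <- as.integer(delta_bp / bw)
  delta <- insulation_delta(track, db)
  strength <- delta_strength(delta, track, db)
  key <- paste0(track$chrom, ":", track$start %/% bw)
  q <- paste0(positions$chrom, ":", positions$pos %/% bw)
  idx <- match(q, key)
  if (anyNA(idx)) stop("position off the chromosomes of the track")
  strength[idx]
}

#' Build the domain tiling from called boundaries
#'
#' Domains tile each chromosome between consecutive boundaries, with
#' chromosome ends as implicit boundaries; a boundary bin belongs to its
#' downstream domain. Boundaries closer than `min_bins` bins to the
#' previous one are dropped (weakest first) so that every domain spans at
#' least `min_bins` bins.
#'
#' @param boundaries output of [call_boundaries()].
#' @param bins bin table of the insulation-resolution matrix.
#' @param min_bins minimum domain span in bins (default 3).
#' @return object of class `tad_set`: list with `boundaries` and `domains`
#'   (`chrom`, `start`, `end` data.frame).
#' @export
tad_set <- function(boundaries, bins, min_bins = 3) {
  bw <- attr(bins, "binwidth")
  if (is.null(bw)) bw <- max(bins$end - bins$start)
  doms <- list()
  kept <- list()
  for (ch in unique(bins$chrom)) {
    chrom_end <- max(bins$end[bins$chrom == ch])
    b <- boundaries[boundaries$chrom == ch, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    # enforce minimum domain span by dropping the weaker of close pairs
    repeat {
      gaps <- diff(c(0, b$start, chrom_end))
      short <- which(gaps < min_bins * bw)
      if (length(short) == 0 || nrow(b) == 0) break
      k <- short[1]
      drop <- if (k == 1) 1
      else if (k > nrow(b)) nrow(b)
      else if (b$strength[k - 1] < b$strength[k]) k - 1 else k
      b <- b[-drop, , drop = FALSE]
    }
    kept[[ch]] <- b
    cuts <- c(0, b$start, chrom_end)
    doms[[ch]] <- data.frame(chrom = ch, start = cuts[-length(cuts)],
                             end = cuts[-1])
  }
  bdf <- do.call(rbind, kept)
  ddf <- do.call(rbind, doms)
  rownames(bdf) <- rownames(ddf) <- NULL
  structure(list(boundaries = bdf, domains = ddf, binwidth = bw),
            class = "tad_set")
}

#' @export
print.tad_set <- function(x, ...) {
  cat(sprintf("tad_set: %d domains (median %.0f kb), %d boundaries\n",
              nrow(x$domains),
              stats::median(x$domains$end - x$domains$start) / 1e3,
              nrow(x$boundaries)))
  invisible(x)
}

#' Flag repressive domains by mark coverage
#'
#' A domain is flagged when the merged peaks of the mark cover strictly
#' more than `min_coverage` of its length (e.g. H3K27me3-covered repressed
#' TADs or H3K9me2-covered heterochromatic TADs).
#'
#' @param tads a `tad_set` (or a domains `data.frame`).
#' @param peaks peak `data.frame` of one mark.
#' @param min_coverage coverage fraction threshold (default 0.5, strict).
#' @return logical vector, one flag per domain.
#' @export
flag_repressive_tads <- function(tads, peaks, min_coverage = 0.5) {
  domains <- if (inherits(tads, "tad_set")) tads$domains else tads
  if (nrow(peaks) == 0) return(rep(FALSE, nrow(domains)))
  pk <- GenomicRanges::reduce(df_granges(peaks))
  dg <- df_granges(domains)
  ov <- GenomicRanges::findOverlaps(dg, pk)
  cov <- numeric(nrow(domains))
  if (length(ov) > 0) {
    inter <- IRanges::pintersect(dg[S4Vectors::queryHits(ov)],
                                 pk[S4Vectors::subjectHits(ov)])
    wsum <- tapply(IRanges::width(inter), S4Vectors::queryHits(ov), sum)
    cov[as.integer(names(wsum))] <- wsum
  }
  cov / (domains$end - domains$start) > min_coverage
}
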