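#' Distance-decay expected model for cis contacts
#'
#' Estimates the background contact probability as a function of genomic
#' distance from the raw counts: distances are pooled into
#' `n_strata` equal-occupancy strata (equal numbers of possible bin
#' pairs), the stratum mean counts are made non-increasing by
#' pool-adjacent-violators (PAVA, weighted by stratum occupancy), and the
#' fit is interpolated linearly in log-distance back onto every integer
#' distance. The per-distance contact probability is the smoothed mean
#' count divided by the total cis count over tested pairs.
#'
#' @param cm raw `contact_matrix` at loop-calling resolution (10 kb in the
#'   standard pipeline).
#' @param n_strata number of equal-occupancy distance strata (default 100).
#' @param min_dist_bins smallest tested separation in bins (default 2;
#'   adjacent bins are dominated by self-ligation artifacts).
#' @return object of class `cis_expected`: `data.frame` `dist`, `mean`
#'   (smoothed mean count per pair), `prob`, plus fields `n_cis` (total
#'   tested cis count) and `min_dist_bins`.
#' @export
expected_cis <- function(cm, n_strata = 100, min_dist_bins = 2) {
  bw <- cm$binwidth
  chroms <- unique(cm$bins$chrom)
  chrom_idx <- split(seq_len(n_bins(cm)), cm$bins$chrom)[chroms]
  max_d <- max(vapply(chrom_idx, length, 0L)) - 1L
  if (max_d < min_dist_bins + 1)
    stop("chromosomes too short for a distance model")
  sum_d <- numeric(max_d + 1L)       # index = d + 1
  npair_d <- numeric(max_d + 1L)
  cnt <- cm$counts
  same <- cm$bins$chrom[cnt$bin1] == cm$bins$chrom[cnt$bin2]
  cis <- cnt[same, , drop = FALSE]
  dd <- cis$bin2 - cis$bin1
  keep <- dd >= min_dist_bins
  s <- rowsum(cis$count[keep], dd[keep])
  sum_d[as.integer(rownames(s)) + 1L] <- s[, 1]
  for (idx in chrom_idx) {
    u <- !cm$mask[idx]
    n <- length(idx)
    for (d in min_dist_bins:(n - 1))
      npair_d[d + 1L] <- npair_d[d + 1L] + sum(u[1:(n - d)] & u[(1 + d):n])
  }
  ds <- which(npair_d > 0) - 1L
  ds <- ds[ds >= min_dist_bins]
  if (length(ds) < 2) stop("chromosomes too short for at least 2 strata")
  # equal-occupancy strata: equal total contact counts per stratum, so the
  # count-dense short distances keep their own strata and the sparse tail
  # is pooled broadly
  occ <- npair_d[ds + 1L]
  cts <- sum_d[ds + 1L]
  cum <- cumsum(cts)
  k <- min(n_strata, length(ds))
  stratum <- pmin(k, floor(cum / (cum[length(cum)] / k)) + 1L)
  stratum <- cummax(stratum)   # guard against zero-count runs
  st_mean <- tapply(sum_d[ds + 1L], stratum, sum) /
    tapply(occ, stratum, sum)
  st_w <- as.numeric(tapply(occ, stratum, sum))
  st_logd <- as.numeric(tapply(log(ds) * occ, stratum, sum)) / st_w
  fit <- pava_nonincreasing(as.numeric(st_mean), st_w)
  mean_d <- stats::approx(st_logd, fit, xout = log(ds), rule = 2)$y
  n_cis <- sum(sum_d[ds + 1L])
  out <- data.frame(dist = ds, mean = mean_d, prob = mean_d / n_cis)
  structure(list(table = out, n_cis = n_cis, min_dist_bins = min_dist_bins,
                 npair_d = npair_d, binwidth = bw),
            class = "cis_expected")
}

# weighted pool-adjacent-violators for a non-increasing fit
pava_nonincreasing <- function(y, w) {
  n <- length(y)
  val <- y; wt <- w; idx <- as.list(seq_len(n))
  i <- 1
  while (i < length(val)) {
    if (val[i] < val[i + 1] - 1e-15) {
      nv <- (val[i] * wt[i] + val[i + 1] * wt[i + 1]) / (wt[i] + wt[i + 1])
      val[i] <- nv; wt[i] <- wt[i] + wt[i + 1]
      idx[[i]] <- c(idx[[i]], idx[[i + 1]])
      val <- val[-(i + 1)]; wt <- wt[-(i + 1)]; idx <- idx[-(i + 1)]
      if (i > 1) i <- i - 1
    } else i <- i + 1
  }
  out <- numeric(n)
  for (k in seq_along(val)) out[idx[[k]]] <- val[k]
  out
}

# look up smoothed per-distance probability (log-linear interpolation
# between fitted distances)
expected_prob_at <- function(exp_model, d) {
  stats::approx(log(exp_model$table$dist), exp_model$table$prob,
                xout = log(d), rule = 2)$y
}

#' Call significant cis loops
#'
#' Fit-Hi-C-style distance-stratified binomial test on raw counts: each
#' tested cis pair (count >= 1, separation >= the model's minimum) gets
#' success probability `p(d) * b_i * b_j`, renormalized so the probability
#' mass over all possible tested pairs is 1, and an upper-tail binomial
#' p-value with `n` = total tested cis count. Benjamini-Hochberg q-values
#' are computed over all tested pairs genome-wide. Significance filters:
#' p-value < `p_cut`, q-value < `q_cut`, and contact count strictly greater
#' than `min_count_gt` (count > 2 with the defaults).
#'
#' @param cm raw `contact_matrix`.
#' @param exp_model from [expected_cis()].
#' @param bias per-bin bias vector from [ice_balance()] (1 where NA /
#'   omitted).
#' @param p_cut,q_cut,min_count_gt significance filters (defaults 0.01,
#'   0.01, 2).
#' @param keep_all return all tested pairs (with a `significant` column)
#'   instead of only the retained loops.
#' @return loop `data.frame`: anchors (`chrom1,start1,end1,chrom2,start2,
#'   end2`), global `bin1`/`bin2`, `count`, `prob` (modeled pair
#'   probability), `pval`, `qval`, `trans = FALSE`.
#' @export
call_cis_loops <- function(cm, exp_model, bias = NULL, p_cut = 0.01,
                           q_cut = 0.01, min_count_gt = 2, keep_all = FALSE) {
  b <- bias_or_one(cm, bias)
  md <- exp_model$min_dist_bins
  chroms <- unique(cm$bins$chrom)
  chrom_idx <- split(seq_len(n_bins(cm)), cm$bins$chrom)[chroms]
  # normalization: sum of p(d) b_i b_j over all possible tested pairs
  z <- 0
  for (idx in chrom_idx) {
    n <- length(idx)
    bb <- b[idx]
    bb[cm$mask[idx]] <- 0
    for (d in md:(n - 1)) {
      sbb <- sum(bb[1:(n - d)] * bb[(1 + d):n])
      if (sbb > 0) z <- z + sbb * expected_prob_at(exp_model, d)
    }
  }
  cnt <- cm$counts
  same <- cm$bins$chrom[cnt$bin1] == cm$bins$chrom[cnt$bin2]
  t <- cnt[same & (cnt$bin2 - cnt$bin1) >= md, , drop = FALSE]
  d <- t$bin2 - t$bin1
  pr <- expected_prob_at(exp_model, d) * b[t$bin1] * b[t$bin2] / z
  n_cis <- exp_model$n_cis
  pval <- stats::pbinom(t$count - 1, n_cis, pr, lower.tail = FALSE)
  qval <- stats::p.adjust(pval, method = "BH")
  res <- loop_frame(cm, t$bin1, t$bin2, t$count, pr, pval, qval, trans = FALSE)
  res$significant <- res$pval < p_cut & res$qval < q_cut &
    res$count > min_count_gt
  if (keep_all) res else {
    out <- res[res$significant, names(res) != "significant", drop = FALSE]
    rownames(out) <- NULL
    out
  }
}

#' Call significant trans loops
#'
#' Same binomial machinery with a uniform (bias-scaled) background: every
#' possible unmasked trans pair has probability proportional to
#' `b_i * b_j`, and `n` = total trans count. The three significance
#' filters are identical to [call_cis_loops()].
#'
#' @inheritParams call_cis_loops
#' @return loop `data.frame` with `trans = TRUE`; empty when the matrix has
#'   no trans counts.
#' @export
call_trans_loops <- function(cm, bias = NULL, p_cut = 0.01, q_cut = 0.01,
                             min_count_gt = 2, keep_all = FALSE) {
  b <- bias_or_one(cm, bias)
  cnt <- cm$counts
  ch <- cm$bins$chrom
  tr <- cnt[ch[cnt$bin1] != ch[cnt$bin2], , drop = FALSE]
  if (nrow(tr) == 0)
    return(loop_frame(cm, integer(0), integer(0), numeric(0), numeric(0),
                      numeric(0), numeric(0), trans = TRUE))
  bb <- b
  bb[cm$mask] <- 0
  sums <- tapply(bb, ch, sum)
  chroms <- names(sums)
  z <- 0
  for (ia in seq_len(length(chroms) - 1)) for (ib in (ia + 1):length(chroms))
    z <- z + sums[[ia]] * sums[[ib]]
  n_trans <- sum(tr$count)
  pr <- b[tr$bin1] * b[tr$bin2] / z
  pval <- stats::pbinom(tr$count - 1, n_trans, pr, lower.tail = FALSE)
  qval <- stats::p.adjust(pval, method = "BH")
  res <- loop_frame(cm, tr$bin1, tr$bin2, tr$count, pr, pval, qval, trans = TRUE)
  res$significant <- res$pval < p_cut & res$qval < q_cut &
    res$count > min_count_gt
  if (keep_all) res else {
    out <- res[res$significant, names(res) != "significant", drop = FALSE]
    rownames(out) <- NULL
    out
  }
}

bias_or_one <- function(cm, bias) {
  if (is.null(bias)) bias <- cm$bias
  if (is.null(bias)) bias <- rep(1, n_bins(cm))
  bias[is.na(bias)] <- 1
  bias
}

loop_frame <- function(cm, bin1, bin2, count, prob, pval, qval, trans) {
  data.frame(chrom1 = cm$bins$chrom[bin1], start1 = cm$bins$start[bin1],
             end1 = cm$bins$end[bin1], chrom2 = cm$bins$chrom[bin2],
             start2 = cm$bins$start[bin2], end2 = cm$bins$end[bin2],
             bin1 = bin1, bin2 = bin2, count = count, prob = prob,
             pval = pval, qval = qval, trans = rep_len(trans, length(bin1)),
             stringsAsFactors = FALSE)
}

#' Fraction of cis loops contained within single TADs
#'
#' A loop is intra-TAD when both anchor bins fall inside the same domain
#' interval of the `tad_set`.
#'
#' @param loops loop `data.frame` (cis rows are used).
#' @param tads a `tad_set`.
#' @return fraction in `[0,1]`; `NA` for an empty cis loop set.
#' @export
intra_tad_fraction <- function(loops, tads) {
  cis <- loops[!loops$trans, , drop = FALSE]
  if (nrow(cis) == 0) return(NA_real_)
  d1 <- domain_of(tads, cis$chrom1, (cis$start1 + cis$end1) %/% 2)
  d2 <- domain_of(tads, cis$chrom2, (cis$start2 + cis$end2) %/% 2)
  mean(!is.na(d1) & !is.na(d2) & d1 == d2)
}

# index of the domain containing each (chrom, pos); NA if none
domain_of <- function(tads, chrom, pos) {
  domains <- if (inherits(tads, "tad_set")) tads$domains else tads
  g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, width = 1L))
  dg <- df_granges(domains)
  ov <- GenomicRanges::findOverlaps(g, dg, select = "first")
  as.integer(ov)
}
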