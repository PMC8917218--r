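#' Call A/B compartments from a balanced contact matrix
#'
#' Classic correlation-matrix PCA, computed per chromosome: the balanced
#' cis map is normalized to observed/expected (expected = mean balanced
#' value at each separation), the Pearson correlation matrix of bin
#' profiles is formed, and its leading eigenvector is the PC1 track. If the
#' leading eigenvector is the trivial all-one-sign vector the next
#' eigenvector is used (logged). The sign is chosen per chromosome so PC1
#' correlates non-negatively with the orientation track (per-bin GC
#' fraction by default, the usual convention: compartment A is GC-rich);
#' bins with positive oriented PC1 are labeled A, negative B, masked or
#' exactly-zero bins NA.
#'
#' @param cm balanced `contact_matrix`, typically at 100-kb resolution
#'   (see [coarsen()] and [ice_balance()]).
#' @param orientation per-bin numeric orientation track, or `"gc"` to use
#'   the bin table's GC column.
#' @param min_bins chromosomes with fewer unmasked bins get an all-NA track
#'   (with a warning).
#' @return `data.frame` (one row per bin): `chrom`, `start`, `end`, `bin`,
#'   `pc1` (oriented), `label` (`"A"`/`"B"`/`NA`), `sign` (orientation sign
#'   applied to that chromosome's eigenvector).
#' @export
call_compartments <- function(cm, orientation = "gc", min_bins = 20) {
  stopifnot(cm$balanced)
  orient <- if (identical(orientation, "gc")) cm$bins$gc else orientation
  stopifnot(length(orient) == n_bins(cm))
  out <- data.frame(chrom = cm$bins$chrom, start = cm$bins$start,
                    end = cm$bins$end, bin = seq_len(n_bins(cm)),
                    pc1 = NA_real_, label = NA_character_, sign = NA_real_,
                    stringsAsFactors = FALSE)
  for (ch in unique(cm$bins$chrom)) {
    sel <- which(cm$bins$chrom == ch)
    d <- cm_dense_chrom(cm, ch)
    u <- which(!cm$mask[sel])
    if (length(u) < min_bins) {
      warning("chromosome ", ch, " has fewer than ", min_bins,
              " unmasked bins; compartment track set to NA")
      next
    }
    oe <- oe_normalize(d)
    m <- oe[u, u, drop = FALSE]
    keep <- apply(m, 2, function(x) {
      s <- stats::sd(x, na.rm = TRUE)
      !is.na(s) && s > 0
    })
    if (sum(keep) < min_bins) next
    cc <- stats::cor(m[keep, keep, drop = FALSE],
                     use = "pairwise.complete.obs")
    cc[!is.finite(cc)] <- 0
    ev <- eigen(cc, symmetric = TRUE)
    v <- ev$vectors[, 1]
    if (all(v > 0) || all(v < 0)) {
      message("leading eigenvector on ", ch,
              " is trivial; using the next eigenvector")
      v <- ev$vectors[, 2]
    }
    s <- stats::cor(v, orient[sel][u][keep])
    s <- if (is.na(s) || s == 0) 1 else sign(s)
    v <- v * s
    idx <- sel[u][keep]
    out$pc1[idx] <- v
    out$sign[idx] <- s
    out$label[idx] <- ifelse(v > 0, "A", ifelse(v < 0, "B", NA))
  }
  out
}

# observed/expected normalization of a dense symmetric cis matrix; the
# expected value at separation d is the mean over non-NA entries of that
# diagonal, so each separation stratum of the result has mean exactly 1.
oe_normalize <- function(d) {
  n <- nrow(d)
  sep <- abs(row(d) - col(d))
  exp_d <- vapply(0:(n - 1), function(k) {
    v <- d[sep == k]
    mean(v, na.rm = TRUE)
  }, numeric(1))
  e <- exp_d[sep + 1]
  oe <- d / e
  oe[!is.finite(oe)] <- NA_real_
  oe
}

#' Genome fractions of compartment labels
#'
#' Bin-width-weighted fractions of the genome labeled A, B, or NA; the
#' three fractions sum to 1.
#'
#' @param track compartment track from [call_compartments()].
#' @return named numeric vector `c(A = , B = , `NA` = )`.
#' @export
compartment_genome_fractions <- function(track) {
  w <- track$end - track$start
  tot <- sum(w)
  a <- sum(w[!is.na(track$label) & track$label == "A"]) / tot
  b <- sum(w[!is.na(track$label) & track$label == "B"]) / tot
  c(A = a, B = b, "NA" = 1 - a - b)
}

#' Merge a compartment track into A/B segments
#'
#' Consecutive same-label bins are merged into BED-style segments.
#'
#' @param track compartment track from [call_compartments()].
#' @return `data.frame` with `chrom`, `start`, `end`, `label`.
#' @export
compartment_segments <- function(track) {
  lab <- ifelse(is.na(track$label), "NA", track$label)
  grp <- cumsum(c(TRUE, lab[-1] != lab[-length(lab)] |
                    track$chrom[-1] != track$chrom[-length(track$chrom)]))
  segs <- do.call(rbind, lapply(split(seq_along(grp), grp), function(ii) {
    data.frame(chrom = track$chrom[ii[1]], start = min(track$start[ii]),
               end = max(track$end[ii]), label = lab[ii[1]])
  }))
  rownames(segs) <- NULL
  segs[segs$label != "NA", , drop = FALSE]
}
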