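#' Annotate loop anchors with regulatory elements and classify loops
#'
#' Each anchor receives every label whose region it overlaps by at least
#' one bp (enhancer with SE/TE subclass, promoter, SuReR/TyReR/SuHeR/TyHeR,
#' CTCF, SMC1). The loop class is assigned by a fixed precedence ladder:
#' `P-P` > `E-P` > `E-E` > `SuReR-SuReR` > `SuReR-TyReR` > `SuHeR-SuHeR` >
#' `SuHeR-TyHeR` > `silencer-mixed` > `CTCF-CTCF` (only when neither anchor
#' carries an enhancer or promoter label — insulator-only loops) > `other`.
#'
#' @param loops loop `data.frame` from the loop caller.
#' @param enhancers classified enhancer elements ([define_enhancers()]).
#' @param promoters promoter set ([define_promoters()]).
#' @param silencers named list with any of `SuReR`, `TyReR`, `SuHeR`,
#'   `TyHeR` element `data.frame`s.
#' @param ctcf,smc1 peak `data.frame`s (may be empty).
#' @return the loops with logical anchor-label columns (`prom1`, `enh1`,
#'   `se1`, `surer1`, ..., same with suffix 2), `class`, and `occupancy`
#'   (`"CTCF&SMC1"`, `"SMC1 only"`, `"CTCF only"`, `"neither"`, from the
#'   union over the two anchors).
#' @export
annotate_anchors <- function(loops, enhancers = NULL, promoters = NULL,
                             silencers = list(), ctcf = NULL, smc1 = NULL) {
  n <- nrow(loops)
  a1 <- GenomicRanges::GRanges(loops$chrom1,
                               IRanges::IRanges(loops$start1 + 1L, loops$end1))
  a2 <- GenomicRanges::GRanges(loops$chrom2,
                               IRanges::IRanges(loops$start2 + 1L, loops$end2))
  hits <- function(anchor, regions) {
    if (is.null(regions) || nrow(regions) == 0) return(rep(FALSE, n))
    GenomicRanges::countOverlaps(anchor, df_granges(regions)) > 0
  }
  enh_se <- if (!is.null(enhancers))
    enhancers[enhancers$super, , drop = FALSE] else NULL
  out <- loops
  out$prom1 <- hits(a1, promoters);   out$prom2 <- hits(a2, promoters)
  out$enh1 <- hits(a1, enhancers);    out$enh2 <- hits(a2, enhancers)
  out$se1 <- hits(a1, enh_se);        out$se2 <- hits(a2, enh_se)
  out$surer1 <- hits(a1, silencers$SuReR); out$surer2 <- hits(a2, silencers$SuReR)
  out$tyrer1 <- hits(a1, silencers$TyReR); out$tyrer2 <- hits(a2, silencers$TyReR)
  out$suher1 <- hits(a1, silencers$SuHeR); out$suher2 <- hits(a2, silencers$SuHeR)
  out$tyher1 <- hits(a1, silencers$TyHeR); out$tyher2 <- hits(a2, silencers$TyHeR)
  out$ctcf1 <- hits(a1, ctcf);        out$ctcf2 <- hits(a2, ctcf)
  out$smc11 <- hits(a1, smc1);        out$smc12 <- hits(a2, smc1)

  sil1 <- out$surer1 | out$tyrer1 | out$suher1 | out$tyher1
  sil2 <- out$surer2 | out$tyrer2 | out$suher2 | out$tyher2
  ep_free <- !(out$enh1 | out$prom1 | out$enh2 | out$prom2)
  cls <- rep("other", n)
  cls[sil1 & sil2] <- "silencer-mixed"
  cls[(out$suher1 & out$tyher2) | (out$tyher1 & out$suher2)] <- "SuHeR-TyHeR"
  cls[out$suher1 & out$suher2] <- "SuHeR-SuHeR"
  cls[(out$surer1 & out$tyrer2) | (out$tyrer1 & out$surer2)] <- "SuReR-TyReR"
  cls[out$surer1 & out$surer2] <- "SuReR-SuReR"
  cls[cls == "other" & ep_free & out$ctcf1 & out$ctcf2] <- "CTCF-CTCF"
  cls[out$enh1 & out$enh2] <- "E-E"
  cls[(out$enh1 & out$prom2) | (out$prom1 & out$enh2)] <- "E-P"
  cls[out$prom1 & out$prom2] <- "P-P"
  out$class <- cls

  has_ctcf <- out$ctcf1 | out$ctcf2
  has_smc1 <- out$smc11 | out$smc12
  out$occupancy <- ifelse(has_ctcf & has_smc1, "CTCF&SMC1",
                          ifelse(has_smc1, "SMC1 only",
                                 ifelse(has_ctcf, "CTCF only", "neither")))
  out
}

#' Expression tier of genes
#'
#' Tiers: `high` for TPM >= 10, `low` for 0.1 <= TPM < 10, `none` for
#' TPM < 0.1; the boundary values 10 and 0.1 belong to the higher tier.
#'
#' @param tpm numeric TPM vector (negative values are an error).
#' @return character vector of tiers.
#' @export
expression_tier <- function(tpm) {
  if (any(tpm < 0)) stop("negative TPM")
  ifelse(tpm >= 10, "high", ifelse(tpm >= 0.1, "low", "none"))
}

#' Occupancy-pattern fractions per loop class
#'
#' Fractions of each loop class with `CTCF&SMC1`, `SMC1 only`, `CTCF only`
#' or `neither` at the anchors (union over the two anchors); fractions per
#' class sum to 1.
#'
#' @param annotated annotated loops ([annotate_anchors()]).
#' @return `data.frame` of fractions, classes in rows.
#' @export
occupancy_pattern <- function(annotated) {
  lv <- c("CTCF&SMC1", "SMC1 only", "CTCF only", "neither")
  tab <- table(annotated$class, factor(annotated$occupancy, levels = lv))
  frac <- prop.table(tab, margin = 1)
  as.data.frame.matrix(frac)
}

#' Fold changes across promoter-promoter loops
#'
#' Maps each anchor of every P-P loop to its overlapped promoter's gene
#' (nearest TSS to the anchor midpoint when several overlap), computes the
#' expression fold change (higher TPM over lower, with a pseudocount added
#' to both) and reports the fractions of pairs exceeding 2- and 10-fold.
#' Anchors without an overlapped gene drop the pair (counted).
#'
#' @param annotated annotated loops; rows with class `P-P` are used.
#' @param promoters promoter set with `tpm`.
#' @param pseudocount TPM pseudocount (default 0.01).
#' @return list: `pairs` (per-loop gene ids, TPMs, `fold`, high/low side),
#'   `frac_gt2`, `frac_gt10`, `n_pairs`, `n_dropped`.
#' @export
pp_fold_changes <- function(annotated, promoters, pseudocount = 0.01) {
  pp <- annotated[annotated$class == "P-P", , drop = FALSE]
  n_drop <- 0L
  rows <- list()
  if (nrow(pp) > 0) {
    g1 <- anchor_gene(pp$chrom1, pp$start1, pp$end1, promoters)
    g2 <- anchor_gene(pp$chrom2, pp$start2, pp$end2, promoters)
    for (k in seq_len(nrow(pp))) {
      if (is.na(g1[k]) || is.na(g2[k])) { n_drop <- n_drop + 1L; next }
      t1 <- promoters$tpm[match(g1[k], promoters$gene_id)]
      t2 <- promoters$tpm[match(g2[k], promoters$gene_id)]
      hi <- max(t1, t2); lo <- min(t1, t2)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_high = if (t1 >= t2) g1[k] else g2[k],
        gene_low = if (t1 >= t2) g2[k] else g1[k],
        tpm_high = hi, tpm_low = lo,
        fold = (hi + pseudocount) / (lo + pseudocount))
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_high = character(), gene_low = character(),
               tpm_high = numeric(), tpm_low = numeric(), fold = numeric())
  list(pairs = pairs,
       frac_gt2 = if (nrow(pairs)) mean(pairs$fold > 2) else NA_real_,
       frac_gt10 = if (nrow(pairs)) mean(pairs$fold > 10) else NA_real_,
       n_pairs = nrow(pairs), n_dropped = n_drop)
}

# gene whose promoter overlaps the anchor; nearest TSS to the anchor
# midpoint breaks ties
anchor_gene <- function(chrom, start, end, promoters) {
  a <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  ov <- GenomicRanges::findOverlaps(a, df_granges(promoters))
  out <- rep(NA_character_, length(a))
  if (length(ov) == 0) return(out)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  mid <- (start + end) / 2
  dist <- abs(promoters$tss[sh] - mid[qh])
  for (q in unique(qh)) {
    cand <- which(qh == q)
    out[q] <- promoters$gene_id[sh[cand[which.min(dist[cand])]]]
  }
  out
}

#' Chromatin-interaction density of regions
#'
#' Number of distinct significant loops with at least one anchor
#' overlapping the region, normalized per `per_bp` of region length
#' (default per 100 kb).
#'
#' @param regions `data.frame` of regions (`chrom`, `start`, `end`).
#' @param loops loop `data.frame`.
#' @param per_bp normalization length (default 1e5).
#' @return numeric density per region.
#' @export
interaction_density <- function(regions, loops, per_bp = 1e5) {
  len <- regions$end - regions$start
  if (any(len <= 0)) stop("zero-length region")
  counts <- loops_touching(regions, loops)
  counts * per_bp / len
}

# distinct-loop count with >= 1 anchor overlapping each region
loops_touching <- function(regions, loops) {
  rg <- df_granges(regions)
  if (nrow(loops) == 0) return(integer(nrow(regions)))
  a1 <- GenomicRanges::GRanges(loops$chrom1,
                               IRanges::IRanges(loops$start1 + 1L, loops$end1))
  a2 <- GenomicRanges::GRanges(loops$chrom2,
                               IRanges::IRanges(loops$start2 + 1L, loops$end2))
  h1 <- GenomicRanges::findOverlaps(rg, a1)
  h2 <- GenomicRanges::findOverlaps(rg, a2)
  pairs <- unique(rbind(
    data.frame(r = S4Vectors::queryHits(h1), l = S4Vectors::subjectHits(h1)),
    data.frame(r = S4Vectors::queryHits(h2), l = S4Vectors::subjectHits(h2))))
  out <- integer(nrow(regions))
  if (nrow(pairs)) {
    t <- table(pairs$r)
    out[as.integer(names(t))] <- as.integer(t)
  }
  out
}

#' Genes looped to a region set
#'
#' A gene is looped to the region set when some loop has one anchor
#' overlapping the gene's promoter and the other anchor overlapping a
#' region. Loops internal to the region set (neither anchor on a promoter)
#' contribute nothing.
#'
#' @param regions region `data.frame` (e.g. SuReR elements).
#' @param loops loop `data.frame`.
#' @param promoters promoter set.
#' @return character vector of gene ids (sorted, unique).
#' @export
genes_looped_to <- function(regions, loops, promoters) {
  if (nrow(loops) == 0 || nrow(regions) == 0 || nrow(promoters) == 0)
    return(character(0))
  rg <- df_granges(regions); pg <- df_granges(promoters)
  a1 <- GenomicRanges::GRanges(loops$chrom1,
                               IRanges::IRanges(loops$start1 + 1L, loops$end1))
  a2 <- GenomicRanges::GRanges(loops$chrom2,
                               IRanges::IRanges(loops$start2 + 1L, loops$end2))
  r1 <- GenomicRanges::countOverlaps(a1, rg) > 0
  r2 <- GenomicRanges::countOverlaps(a2, rg) > 0
  genes <- character(0)
  h1 <- GenomicRanges::findOverlaps(a1, pg)
  h2 <- GenomicRanges::findOverlaps(a2, pg)
  if (length(h1))
    genes <- c(genes, promoters$gene_id[
      S4Vectors::subjectHits(h1)[r2[S4Vectors::queryHits(h1)]]])
  if (length(h2))
    genes <- c(genes, promoters$gene_id[
      S4Vectors::subjectHits(h2)[r1[S4Vectors::queryHits(h2)]]])
  sort(unique(genes))
}

#' Containment of E-P loops in CTCF-CTCF loop domains
#'
#' Each cis CTCF-CTCF loop spans a domain from the start of its first
#' anchor to the end of its second (anchors inclusive) — the candidate
#' insulated neighborhood. An E-P loop is contained when both of its
#' anchors lie inside a single such domain. CTCF-CTCF loops are themselves
#' classified against a `tad_set` as `boundary-anchored` (an anchor in a
#' boundary bin), `intra-TAD` or `inter-TAD`.
#'
#' @param ep_loops annotated loops of class `E-P` (any loop frame works).
#' @param ctcf_loops annotated loops of class `CTCF-CTCF`.
#' @param tads optional `tad_set` for the CTCF-loop classification.
#' @return list: `fraction` (of E-P loops contained), `contained` logical
#'   per E-P loop, `ctcf_class` per CTCF-CTCF loop (when `tads` given).
#' @export
containment_in_ctcf_domains <- function(ep_loops, ctcf_loops, tads = NULL) {
  cis <- ctcf_loops[!ctcf_loops$trans, , drop = FALSE]
  domains <- data.frame(chrom = cis$chrom1, start = cis$start1,
                        end = cis$end2, stringsAsFactors = FALSE)
  contained <- rep(FALSE, nrow(ep_loops))
  if (nrow(ep_loops) > 0 && nrow(domains) > 0) {
    dg <- df_granges(domains)
    a1 <- GenomicRanges::GRanges(ep_loops$chrom1,
                                 IRanges::IRanges(ep_loops$start1 + 1L, ep_loops$end1))
    a2 <- GenomicRanges::GRanges(ep_loops$chrom2,
                                 IRanges::IRanges(ep_loops$start2 + 1L, ep_loops$end2))
    h1 <- GenomicRanges::findOverlaps(a1, dg, type = "within")
    h2 <- GenomicRanges::findOverlaps(a2, dg, type = "within")
    k1 <- paste(S4Vectors::queryHits(h1), S4Vectors::subjectHits(h1))
    k2 <- paste(S4Vectors::queryHits(h2), S4Vectors::subjectHits(h2))
    both <- intersect(k1, k2)
    contained[unique(as.integer(sub(" .*", "", both)))] <- TRUE
  }
  res <- list(fraction = if (nrow(ep_loops)) mean(contained) else NA_real_,
              contained = contained)
  if (!is.null(tads) && nrow(cis) > 0) {
    bb <- tads$boundaries
    bnd <- if (nrow(bb) > 0)
      GenomicRanges::GRanges(bb$chrom, IRanges::IRanges(bb$start + 1L, bb$end))
    else GenomicRanges::GRanges()
    a1 <- GenomicRanges::GRanges(cis$chrom1,
                                 IRanges::IRanges(cis$start1 + 1L, cis$end1))
    a2 <- GenomicRanges::GRanges(cis$chrom2,
                                 IRanges::IRanges(cis$start2 + 1L, cis$end2))
    on_bnd <- GenomicRanges::countOverlaps(a1, bnd) > 0 |
      GenomicRanges::countOverlaps(a2, bnd) > 0
    d1 <- domain_of(tads, cis$chrom1, (cis$start1 + cis$end1) %/% 2)
    d2 <- domain_of(tads, cis$chrom2, (cis$start2 + cis$end2) %/% 2)
    res$ctcf_class <- ifelse(on_bnd, "boundary-anchored",
                             ifelse(!is.na(d1) & !is.na(d2) & d1 == d2,
                                    "intra-TAD", "inter-TAD"))
  }
  res
}

#' Loop-length summaries per class
#'
#' Length of a cis loop is `start2 - start1` (anchor-start distance).
#' Trans loops are excluded and counted.
#'
#' @param annotated annotated loops with a `class` column.
#' @return list: `stats` data.frame (class, n, median, q1, q3),
#'   `n_trans_excluded`.
#' @export
loop_length_stats <- function(annotated) {
  cis <- annotated[!annotated$trans, , drop = FALSE]
  len <- cis$start2 - cis$start1
  st <- do.call(rbind, lapply(split(len, cis$class), function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(n = length(v), q1 = q[1], median = q[2], q3 = q[3])
  }))
  st$class <- rownames(st)
  rownames(st) <- NULL
  list(stats = st[, c("class", "n", "q1", "median", "q3")],
       n_trans_excluded = sum(annotated$trans))
}
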