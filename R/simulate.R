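#' Specification for a synthetic 3D genome
#'
#' Collects the parameters of the synthetic-genome generator: a toy genome
#' whose Hi-C contact map carries a power-law distance decay, an alternating
#' A/B compartment checkerboard, block-diagonal TAD enrichment, and focal
#' enrichment at planted loop anchors, with co-located peak tracks
#' (H3K27ac/H3K27me3/H3K9me2/H3K4me3/CTCF/SMC1/EP300) and a three-tier
#' expression table. All multiplicative strengths are relative to the
#' distance-decay baseline and must be `>= 1`.
#'
#' The expected count of a cis bin pair `(i,j)` at separation `d = |i-j| >= 1`
#' is `lambda * d^(-alpha) * C * T * F`, where `C = compartment_strength` if
#' the bins share a compartment label (else 1), `T = tad_strength` if they
#' share a planted TAD (else 1), and `F = loop_strength` if `(i,j)` is a
#' planted loop pair (1-bin footprint). Observed counts are independent
#' Poisson draws (optionally Gamma-Poisson when `overdispersion > 0`); trans
#' pairs use the constant mean `lambda_trans`; the diagonal is zero.
#'
#' @param chrom_lengths named chromosome lengths (bp).
#' @param binwidth matrix bin width (bp).
#' @param alpha distance-decay exponent.
#' @param lambda expected count of an adjacent-bin cis pair.
#' @param lambda_trans expected count of a trans pair.
#' @param compartment_block compartment block size (bp), alternating A/B.
#' @param compartment_strength multiplicative same-compartment enrichment.
#' @param tad_length_range min/max planted TAD length (bp); lengths are drawn
#'   on a grid of `4 * binwidth` so domain boundaries sit on the coarser
#'   resolution at which domains are typically called.
#' @param tad_strength multiplicative within-TAD enrichment.
#' @param loop_strength multiplicative focal enrichment at planted loop pairs.
#' @param n_genes total number of genes.
#' @param tier_fractions expression-tier probabilities (high / low / none;
#'   tiers are TPM >= 10, [0.1, 10), < 0.1).
#' @param overdispersion Gamma-Poisson overdispersion (0 = pure Poisson).
#' @param seed master RNG seed; per-artifact streams are derived from it by
#'   fixed offsets, so regenerating one artifact does not shift the others.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(chrom_lengths = c(chr1 = 20e6, chr2 = 20e6),
                           binwidth = 1e4,
                           alpha = 1.0,
                           lambda = 50,
                           lambda_trans = 0.02,
                           compartment_block = 1e6,
                           compartment_strength = 1.6,
                           tad_length_range = c(0.3e6, 1.2e6),
                           tad_strength = 2.0,
                           loop_strength = 6.0,
                           n_genes = 500,
                           tier_fractions = c(high = 0.4, low = 0.4, none = 0.2),
                           overdispersion = 0,
                           seed = 1) {
  stopifnot(length(chrom_lengths) >= 1, !is.null(names(chrom_lengths)),
            binwidth >= 1000, alpha > 0, lambda > 0, lambda_trans >= 0,
            compartment_strength >= 1, tad_strength >= 1, loop_strength >= 1,
            n_genes >= 0, length(tier_fractions) == 3,
            abs(sum(tier_fractions) - 1) < 1e-8, overdispersion >= 0)
  if (compartment_block %% binwidth != 0)
    stop("compartment_block must be a multiple of binwidth")
  if (tad_length_range[1] < 3 * binwidth)
    stop("planted TAD segments must be at least 3 bins long")
  if (any(chrom_lengths %% compartment_block != 0))
    stop("chromosome lengths must be multiples of the compartment block size")
  structure(list(chrom_lengths = chrom_lengths, binwidth = binwidth,
                 alpha = alpha, lambda = lambda, lambda_trans = lambda_trans,
                 compartment_block = compartment_block,
                 compartment_strength = compartment_strength,
                 tad_length_range = tad_length_range,
                 tad_strength = tad_strength, loop_strength = loop_strength,
                 n_genes = n_genes,
                 tier_fractions = stats::setNames(tier_fractions,
                                                  c("high", "low", "none")),
                 overdispersion = overdispersion, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Split `U` grid units into segment lengths in [lmin, lmax] such that no
# remainder smaller than lmin is left over.
segment_units <- function(U, lmin, lmax) {
  if (U < lmin) return(U)        # degenerate tail: one short segment
  lens <- integer(0)
  rem <- U
  while (rem > 0) {
    cand <- lmin:min(lmax, rem)
    cand <- cand[rem - cand == 0 | rem - cand >= lmin]
    l <- if (length(cand) == 1) cand else sample(cand, 1)
    lens <- c(lens, l)
    rem <- rem - l
  }
  lens
}

#' Plant the ground-truth structure of a synthetic genome
#'
#' Deterministically (given the spec seed) lays out compartments, TADs,
#' loops, regulatory elements and genes. Compartment blocks alternate A/B
#' (the first block of odd-numbered chromosomes is A); planted TAD
#' boundaries nest inside compartment blocks, so every compartment edge is
#' also a TAD boundary, as in real genomes. Within selected A-compartment
#' TADs the generator plants super-enhancer hubs (three SEs and a promoter
#' joined by SE-SE and SE-P loops inside a flanking CTCF-CTCF loop),
#' standalone SE-P pairs, typical-enhancer E-P and E-E loops, and P-P
#' loops; one B block per chromosome hosts dense H3K27me3 domains (SuReR)
#' and another dense H3K9me2 domains (SuHeR), with silencer loops and
#' silencer-looped silent genes. Structural CTCF-CTCF loop anchors carry no
#' enhancer or promoter.
#'
#' @param spec a [synthetic_spec()].
#' @return object of class `ground_truth`: bin table with compartment-
#'   dependent GC, per-bin compartment labels and TAD ids, TAD domains and
#'   boundaries, planted loops with classes, element intervals per mark,
#'   peak templates, and genes with expression tiers.
#' @export
plant_structure <- function(spec) {
  set.seed(spec$seed + 1L)
  bw <- spec$binwidth
  grid <- 4L * bw                          # TAD boundary grid
  gbins <- as.integer(grid / bw)           # bins per grid unit
  lmin_u <- max(1L, as.integer(round(spec$tad_length_range[1] / grid)))
  lmax_u <- max(lmin_u, as.integer(round(spec$tad_length_range[2] / grid)))
  chroms <- names(spec$chrom_lengths)
  bins <- make_bins(spec$chrom_lengths, bw)
  nbin <- nrow(bins)
  comp <- character(nbin)
  tad_id <- integer(nbin)
  offsets <- c(0L, cumsum(vapply(chroms, function(ch)
    as.integer(spec$chrom_lengths[[ch]] / bw), 0L)))
  names(offsets) <- c(chroms, "..")

  tads <- list(); bounds <- list(); loops <- list()
  elements <- list(); peaks <- list(); genes <- list()
  elem_n <- 0L; gene_n <- 0L; tad_n <- 0L

  add_peak <- function(chrom, start, end, mark, signal_base, element = NA) {
    peaks[[length(peaks) + 1L]] <<- data.frame(
      chrom = chrom, start = start, end = end, mark = mark,
      signal_base = signal_base, element_id = element)
  }
  add_element <- function(chrom, start, end, mark, class) {
    elem_n <<- elem_n + 1L
    id <- sprintf("%s_%d", class, elem_n)
    elements[[length(elements) + 1L]] <<- data.frame(
      chrom = chrom, start = start, end = end, mark = mark, class = class,
      id = id)
    id
  }
  add_gene <- function(chrom, tss, tier, role) {
    gene_n <<- gene_n + 1L
    len <- sample(2000:30000, 1)
    strand <- sample(c("+", "-"), 1)
    if (strand == "+") { start <- tss; end <- min(tss + len, spec$chrom_lengths[[chrom]]) }
    else { start <- max(0, tss - len + 1); end <- tss + 1 }
    genes[[length(genes) + 1L]] <<- data.frame(
      chrom = chrom, start = start, end = end, strand = strand,
      gene_id = sprintf("g%04d", gene_n), tier = tier, role = role)
    invisible(gene_n)
  }
  add_loop <- function(chrom, b1, b2, class) {
    loops[[length(loops) + 1L]] <<- data.frame(
      chrom = chrom, lbin1 = min(b1, b2), lbin2 = max(b1, b2), class = class)
  }

  # dense tiling of one repressive mark across [from_bin, to_bin) local bins
  tile_mark <- function(chrom, off_bp, from, to, mark, pw, gap, sig, class) {
    span0 <- off_bp + (from - 1L) * bw
    span1 <- off_bp + (to - 1L) * bw
    starts <- seq(span0, span1 - pw, by = pw + gap)
    id <- add_element(chrom, starts[1], starts[length(starts)] + pw, mark, class)
    for (s in starts) add_peak(chrom, s, s + pw, mark, sig, id)
    id
  }

  occupied <- vector("list", length(chroms))   # local bins already used
  names(occupied) <- chroms

  for (ic in seq_along(chroms)) {
    ch <- chroms[ic]
    len <- spec$chrom_lengths[[ch]]
    nloc <- as.integer(len / bw)
    block_u <- as.integer(spec$compartment_block / grid)
    nblock <- as.integer(len / spec$compartment_block)
    block_label <- ifelse(((seq_len(nblock) + ic) %% 2) == 0, "A", "B")
    b_blocks <- which(block_label == "B")
    silencer_block <- if (length(b_blocks) >= 2) b_blocks[2] else NA
    hetero_block <- if (length(b_blocks) >= 4) b_blocks[4] else NA

    # --- compartments and TAD segmentation (nested in blocks) ---
    comp_loc <- rep(block_label, each = as.integer(spec$compartment_block / bw))
    comp[offsets[ic] + seq_len(nloc)] <- comp_loc[seq_len(nloc)]
    tad_of_block <- vector("list", nblock)
    tstart_u <- 0L
    for (ib in seq_len(nblock)) {
      lens_u <- if (!is.na(silencer_block) && ib %in% c(silencer_block, hetero_block) &&
                    17L >= lmin_u && block_u - 17L >= lmin_u && 17L <= lmax_u)
        c(17L, segment_units(block_u - 17L, lmin_u, lmax_u))
      else segment_units(block_u, lmin_u, lmax_u)
      ids <- integer(length(lens_u))
      cur <- tstart_u
      for (k in seq_along(lens_u)) {
        tad_n <- tad_n + 1L
        s_bin <- cur * gbins + 1L
        e_bin <- (cur + lens_u[k]) * gbins
        tads[[tad_n]] <- data.frame(chrom = ch, start = (s_bin - 1L) * bw,
                                    end = e_bin * bw, id = tad_n,
                                    units = lens_u[k], block = ib,
                                    label = block_label[ib])
        tad_id[offsets[ic] + s_bin:e_bin] <- tad_n
        ids[k] <- tad_n
        cur <- cur + lens_u[k]
      }
      tad_of_block[[ib]] <- ids
      tstart_u <- tstart_u + block_u
    }

    mark_used <- function(from, to) {
      occupied[[ch]] <<- c(occupied[[ch]], seq(max(1L, from), min(nloc, to)))
    }
    bp0 <- function(lb) (lb - 1L) * bw   # local bin -> bp start

    # --- role assignment among A-compartment TADs ---
    ctad <- do.call(rbind, tads[unlist(tad_of_block)])
    atads <- ctad[ctad$label == "A", ]
    atads <- atads[order(-atads$units), ]
    if (nrow(atads) < 5)
      stop("chromosome ", ch, " too small to host the planted element layout")
    # full layout on a >= 20 Mb chromosome; trimmed from the tail on smaller
    roles <- c("hub", "hub", "standalone", "ee", "tep", "tep", "pp_big",
               "pp_small", "tep", "tep")
    roles <- roles[seq_len(min(length(roles), nrow(atads)))]
    atads <- atads[seq_along(roles), ]
    atads$role <- roles

    plant_se <- function(lb) {   # SE = 5 stitched peaks spanning ~25 kb
      s <- bp0(lb) + 2000
      starts <- s + (0:4) * 5500
      id <- add_element(ch, starts[1], starts[5] + 3000, "H3K27ac", "SE")
      for (p in starts) {
        add_peak(ch, p, p + 3000, "H3K27ac", 25, id)
        add_peak(ch, p, p + 3000, "EP300", 10, id)
      }
      id
    }
    plant_te <- function(lb) {
      s <- bp0(lb) + 4000
      id <- add_element(ch, s, s + 1500, "H3K27ac", "TE")
      add_peak(ch, s, s + 1500, "H3K27ac", 3, id)
      id
    }
    plant_prom_gene <- function(lb, tier, role, k27ac = FALSE) {
      tss <- bp0(lb) + 5000
      add_gene(ch, tss, tier, role)
      if (k27ac) add_peak(ch, tss - 500, tss + 500, "H3K27ac", 6, NA)
      tss
    }
    plant_ctcf_pair <- function(a1, a2) {
      for (a in c(a1, a2)) {
        p <- bp0(a) + 4600
        add_peak(ch, p, p + 800, "CTCF", 12, NA)
        add_peak(ch, p, p + 800, "SMC1", 10, NA)
      }
      add_loop(ch, a1, a2, "ctcf")
    }

    for (r in seq_len(nrow(atads))) {
      ts <- as.integer(atads$start[r] / bw) + 1L   # local first bin of TAD
      L <- atads$units[r] * gbins
      role <- atads$role[r]
      if (role == "hub") {
        o <- ts + max(5L, (L - 30L) %/% 2L)
        s1 <- o; s2 <- o + 8L; s3 <- o + 16L; p <- o + 24L
        for (sb in c(s1, s2, s3)) plant_se(sb)
        plant_prom_gene(p, "high", "hub_promoter")
        add_loop(ch, s1, s2, "se_se"); add_loop(ch, s2, s3, "se_se")
        add_loop(ch, s1, s3, "se_se"); add_loop(ch, s3, p, "se_p")
        plant_ctcf_pair(o - 3L, o + 27L)
        mark_used(o - 5L, o + 29L)
      } else if (role == "standalone") {
        s <- ts + 5L; p <- s + 10L
        plant_se(s); plant_prom_gene(p, "high", "se_target")
        add_loop(ch, s, p, "se_p")
        plant_ctcf_pair(s - 3L, p + 3L)
        mark_used(s - 5L, p + 5L)
      } else if (role == "tep") {
        e <- ts + 5L; d <- sample(6:12, 1); p <- e + d
        plant_te(e); plant_prom_gene(p, "high", "ep_target", k27ac = TRUE)
        add_loop(ch, e, p, "ep")
        plant_ctcf_pair(e - 3L, p + 3L)
        mark_used(e - 5L, p + 5L)
      } else if (role == "ee") {
        e1 <- ts + 5L; e2 <- e1 + 8L; e3 <- e1 + 16L
        for (eb in c(e1, e2, e3)) plant_te(eb)
        add_loop(ch, e1, e2, "ee"); add_loop(ch, e2, e3, "ee")
        plant_ctcf_pair(e1 - 3L, e3 + 3L)
        mark_used(e1 - 5L, e3 + 5L)
      } else {                                  # P-P loop pair
        p1 <- ts + 4L; d <- sample(6:12, 1); p2 <- p1 + d
        if (role == "pp_big") { t1 <- "high"; t2 <- "low_weak" }
        else { t1 <- "high_weak"; t2 <- "low" }
        plant_prom_gene(p1, t1, "pp")
        plant_prom_gene(p2, t2, "pp")
        add_loop(ch, p1, p2, "pp")
        mark_used(p1 - 2L, p2 + 2L)
      }
    }

    # --- silencer (H3K27me3 / SuReR) block ---
    if (!is.na(silencer_block)) {
      stad <- tad_of_block[[silencer_block]][1]
      s <- as.integer(tads[[stad]]$start / bw) + 1L
      id1 <- tile_mark(ch, 0, s + 6L, s + 36L, "H3K27me3", 4000, 1000, 10, "SuReR")
      id2 <- tile_mark(ch, 0, s + 42L, s + 60L, "H3K27me3", 4000, 1000, 10, "SuReR")
      plant_prom_gene(s + 38L, "none", "surer_looped")
      add_loop(ch, s + 20L, s + 50L, "surer_surer")
      add_loop(ch, s + 38L, s + 20L, "prom_surer")
      for (a in c(s + 20L, s + 50L)) {   # CTCF/SMC1 at silencer loop anchors
        p <- bp0(a) + 4600
        add_peak(ch, p, p + 800, "CTCF", 8, NA)
        add_peak(ch, p, p + 800, "SMC1", 7, NA)
      }
      # typical cluster in the next TAD of the block, looped to SuReR2
      ty_tad <- tad_of_block[[silencer_block]][2]
      tyb <- as.integer(tads[[ty_tad]]$start / bw) + 4L
      tile_mark(ch, 0, tyb, tyb + 2L, "H3K27me3", 4000, 1000, 5, "TyReR")
      add_loop(ch, s + 50L, tyb, "surer_tyrer")
      mark_used(s + 4L, s + 62L); mark_used(tyb - 2L, tyb + 4L)
      # overlapping dense H3K9me2 (one SuReR/SuHeR overlap per odd chromosome)
      if (ic %% 2 == 1)
        tile_mark(ch, 0, s + 30L, s + 40L, "H3K9me2", 4000, 800, 10, "SuHeR")
    }

    # --- heterochromatin (H3K9me2 / SuHeR) block ---
    if (!is.na(hetero_block)) {
      htad <- tad_of_block[[hetero_block]][1]
      h <- as.integer(tads[[htad]]$start / bw) + 1L
      tile_mark(ch, 0, h + 6L, h + 34L, "H3K9me2", 4000, 800, 10, "SuHeR")
      tile_mark(ch, 0, h + 40L, h + 56L, "H3K9me2", 4000, 800, 10, "SuHeR")
      plant_prom_gene(h + 37L, "none", "suher_looped")
      add_loop(ch, h + 20L, h + 48L, "suher_suher")
      add_loop(ch, h + 37L, h + 20L, "prom_suher")
      mark_used(h + 4L, h + 58L)
    }

    # --- scattered typical silencer clusters and typical enhancers ---
    free_b_bins <- setdiff(
      which(comp_loc == "B"),
      c(occupied[[ch]],
        if (!is.na(silencer_block)) which(ceiling(seq_len(nloc) * bw / spec$compartment_block) %in%
                                            c(silencer_block, hetero_block))))
    scatter_cluster <- function(n, mark, class, sig) {
      for (k in seq_len(n)) {
        if (length(free_b_bins) < 8) break
        lb <- sample(free_b_bins, 1)
        tile_mark(ch, 0, lb, lb + 1L, mark, 4000, 1000, sig, class)
        free_b_bins <<- setdiff(free_b_bins, (lb - 3L):(lb + 4L))
        mark_used(lb - 2L, lb + 3L)
      }
    }
    scatter_cluster(15, "H3K27me3", "TyReR", 5)
    scatter_cluster(12, "H3K9me2", "TyHeR", 5)

    free_a_bins <- setdiff(which(comp_loc == "A"), occupied[[ch]])
    for (k in seq_len(20)) {
      if (length(free_a_bins) < 4) break
      lb <- sample(free_a_bins, 1)
      plant_te(lb)
      free_a_bins <- setdiff(free_a_bins, (lb - 3L):(lb + 3L))
      mark_used(lb - 2L, lb + 2L)
    }

    # CTCF/SMC1 at every planted TAD boundary, plus scattered CTCF-only sites
    cdf <- do.call(rbind, tads[unlist(tad_of_block)])
    internal <- cdf$start[cdf$start > 0]
    for (b in internal) {
      add_peak(ch, b - 400, b + 400, "CTCF", 12, NA)
      add_peak(ch, b - 400, b + 400, "SMC1", 9, NA)
    }
    free_a_bins <- setdiff(free_a_bins, occupied[[ch]])
    for (k in seq_len(10)) {
      if (length(free_a_bins) < 2) break
      lb <- sample(free_a_bins, 1)
      add_peak(ch, bp0(lb) + 4600, bp0(lb) + 5400, "CTCF", 6, NA)
      free_a_bins <- setdiff(free_a_bins, (lb - 2L):(lb + 2L))
      mark_used(lb - 1L, lb + 1L)
    }
  }

  tads <- do.call(rbind, tads)
  elements <- do.call(rbind, elements)
  peaks_df <- do.call(rbind, peaks)
  loops <- do.call(rbind, loops)
  genes <- do.call(rbind, genes)

  # --- scattered background genes, tiers drawn iid from the spec fractions ---
  n_scatter <- max(0L, spec$n_genes - nrow(genes))
  if (n_scatter > 0) {
    chrom_vec <- rep(names(spec$chrom_lengths),
                     round(n_scatter * spec$chrom_lengths / sum(spec$chrom_lengths)))
    chrom_vec <- chrom_vec[seq_len(min(length(chrom_vec), n_scatter))]
    counts <- table(factor(chrom_vec, levels = chroms))
    extra <- list()
    for (ic in seq_along(chroms)) {
      ch <- chroms[ic]
      nloc <- as.integer(spec$chrom_lengths[[ch]] / bw)
      occ <- unique(pmin(pmax(occupied[[ch]], 1L), nloc))
      allowed <- setdiff(seq_len(nloc), unique(c(occ, occ + 1L, occ - 1L)))
      nken <- counts[[ch]]
      lbs <- sample(allowed, min(nken, length(allowed)))
      tiers <- sample(names(spec$tier_fractions), length(lbs), replace = TRUE,
                      prob = spec$tier_fractions)
      for (k in seq_along(lbs)) {
        gene_n <- gene_n + 1L
        tss <- (lbs[k] - 1L) * bw + sample(2000:8000, 1)
        len <- sample(2000:30000, 1)
        strand <- sample(c("+", "-"), 1)
        if (strand == "+") { st <- tss; en <- min(tss + len, spec$chrom_lengths[[ch]]) }
        else { st <- max(0, tss - len + 1); en <- tss + 1 }
        extra[[length(extra) + 1L]] <- data.frame(
          chrom = ch, start = st, end = en, strand = strand,
          gene_id = sprintf("g%04d", gene_n), tier = tiers[k],
          role = "background")
      }
    }
    genes <- rbind(genes, do.call(rbind, extra))
  }

  # GC track: compartment A slightly GC-richer, the usual orientation cue
  gc <- ifelse(comp == "A", stats::rnorm(nbin, 0.45, 0.008),
               stats::rnorm(nbin, 0.40, 0.008))
  bins$gc <- pmin(pmax(gc, 0), 1)

  loops$bin1 <- offsets[loops$chrom] + loops$lbin1
  loops$bin2 <- offsets[loops$chrom] + loops$lbin2
  boundaries <- tads[tads$start > 0, c("chrom", "start")]
  names(boundaries) <- c("chrom", "pos")
  rownames(tads) <- rownames(boundaries) <- rownames(loops) <- NULL
  rownames(elements) <- rownames(peaks_df) <- rownames(genes) <- NULL

  structure(list(spec = spec, bins = bins, compartment = comp,
                 tad_id = tad_id, tads = tads, boundaries = boundaries,
                 loops = loops, elements = elements,
                 peak_templates = peaks_df, genes = genes),
            class = "ground_truth")
}

#' Simulate a raw Hi-C contact matrix with planted structure
#'
#' Plants the ground-truth structure (see [plant_structure()]) and draws
#' Poisson counts around the multiplicative expected model described in
#' [synthetic_spec()]. Fully deterministic for a fixed spec seed.
#'
#' @param spec a [synthetic_spec()].
#' @param truth optional pre-planted `ground_truth` (must come from the same
#'   spec); planted afresh when omitted.
#' @return `list(matrix = contact_matrix, truth = ground_truth)`.
#' @export
simulate_contacts <- function(spec, truth = NULL) {
  if (is.null(truth)) truth <- plant_structure(spec)
  set.seed(spec$seed + 2L)
  bw <- spec$binwidth
  chroms <- names(spec$chrom_lengths)
  nloc <- as.integer(spec$chrom_lengths / bw)
  offsets <- c(0L, cumsum(nloc))
  trip <- list()
  for (ic in seq_along(chroms)) {
    n <- nloc[ic]; off <- offsets[ic]
    j <- rep.int(2:n, times = 1:(n - 1))
    i <- sequence(1:(n - 1))
    d <- j - i
    mu <- spec$lambda * d^(-spec$alpha)
    gi <- off + i; gj <- off + j
    same_comp <- truth$compartment[gi] == truth$compartment[gj]
    mu[same_comp] <- mu[same_comp] * spec$compartment_strength
    same_tad <- truth$tad_id[gi] == truth$tad_id[gj] & truth$tad_id[gi] > 0
    mu[same_tad] <- mu[same_tad] * spec$tad_strength
    lp <- truth$loops[truth$loops$chrom == chroms[ic], ]
    if (nrow(lp) > 0) {
      key <- (as.numeric(gi) - 1) * (sum(nloc) + 1) + as.numeric(gj)
      lkey <- (as.numeric(lp$bin1) - 1) * (sum(nloc) + 1) + as.numeric(lp$bin2)
      hit <- key %in% lkey
      mu[hit] <- mu[hit] * spec$loop_strength
    }
    if (spec$overdispersion > 0)
      mu <- mu * stats::rgamma(length(mu), shape = 1 / spec$overdispersion,
                               scale = spec$overdispersion)
    cnt <- stats::rpois(length(mu), mu)
    keep <- cnt > 0
    trip[[ic]] <- data.frame(bin1 = gi[keep], bin2 = gj[keep],
                             count = cnt[keep])
  }
  # trans: constant background mean
  if (length(chroms) > 1 && spec$lambda_trans > 0) {
    for (ia in seq_len(length(chroms) - 1)) for (ib in (ia + 1):length(chroms)) {
      na <- nloc[ia]; nb <- nloc[ib]
      cnt <- stats::rpois(na * nb, spec$lambda_trans)
      keep <- which(cnt > 0)
      if (length(keep)) {
        i <- offsets[ia] + ((keep - 1L) %% na) + 1L
        j <- offsets[ib] + ((keep - 1L) %/% na) + 1L
        trip[[length(trip) + 1L]] <- data.frame(bin1 = i, bin2 = j,
                                                count = cnt[keep])
      }
    }
  }
  cm <- contact_matrix(truth$bins, do.call(rbind, trip), balanced = FALSE)
  list(matrix = cm, truth = truth)
}

#' Simulate epigenomic peak tracks and the gene expression table
#'
#' Materializes the planted peak templates with log-normal signal jitter and
#' draws gene TPMs within each gene's planted tier (high: `10^U(1,3)`;
#' low: `10^U(-1, ~1)`; none: `U(0, 0.099)`). H3K4me3 peaks are added at the
#' promoters of expressed (high or low tier) genes. Uses RNG streams
#' distinct from the contact-matrix stream.
#'
#' @param spec a [synthetic_spec()].
#' @param truth the `ground_truth` from [plant_structure()] /
#'   [simulate_contacts()].
#' @return `list(peaks = named list of peak data.frames by mark,
#'   genes = gene table with tpm)`.
#' @export
simulate_tracks <- function(spec, truth) {
  set.seed(spec$seed + 3L)
  pt <- truth$peak_templates
  pt$signal <- pt$signal_base * exp(stats::rnorm(nrow(pt), 0, 0.2))
  set.seed(spec$seed + 4L)
  g <- truth$genes
  tpm <- numeric(nrow(g))
  base_tier <- sub("_weak", "", g$tier)
  hi <- base_tier == "high"; lo <- base_tier == "low"; no <- base_tier == "none"
  tpm[hi] <- 10^stats::runif(sum(hi), 1, 3)
  tpm[lo] <- 10^stats::runif(sum(lo), -1, 0.9995)
  tpm[no] <- stats::runif(sum(no), 0, 0.099)
  # planted P-P pairs with controlled fold change: weak variants sit close
  # to the tier boundary so one pair per chromosome stays below 10-fold
  tpm[g$tier == "high_weak"] <- 10^stats::runif(sum(g$tier == "high_weak"), 1.2, 1.5)
  tpm[g$tier == "low_weak"] <- 10^stats::runif(sum(g$tier == "low_weak"), -0.2, 0.2)
  g$tpm <- tpm
  g$tier <- base_tier
  expressed <- g[base_tier %in% c("high", "low"), ]
  if (nrow(expressed) > 0) {
    tss <- ifelse(expressed$strand == "+", expressed$start, expressed$end - 1L)
    k4 <- data.frame(chrom = expressed$chrom,
                     start = pmax(0, tss - 1000), end = tss + 1000,
                     mark = "H3K4me3", signal_base = 8, element_id = NA,
                     signal = 8 * exp(stats::rnorm(nrow(expressed), 0, 0.2)))
    pt <- rbind(pt, k4)
  }
  marks <- split(pt[, c("chrom", "start", "end", "signal", "element_id")],
                 pt$mark)
  marks <- lapply(marks, function(df) {
    df <- df[order(df$chrom, df$start), ]
    df$name <- sprintf("pk%d", seq_len(nrow(df)))
    rownames(df) <- NULL
    df[, c("chrom", "start", "end", "name", "signal", "element_id")]
  })
  g$tss <- ifelse(g$strand == "+", g$start, g$end - 1L)
  list(peaks = marks, genes = g)
}

#' Simulate a complete synthetic genome
#'
#' Convenience wrapper running [plant_structure()], [simulate_contacts()]
#' and [simulate_tracks()] under one spec.
#'
#' @param spec a [synthetic_spec()] (defaults to the standard toy genome).
#' @return list with `spec`, `truth`, `matrix`, `peaks`, `genes`.
#' @export
simulate_genome <- function(spec = synthetic_spec()) {
  sim <- simulate_contacts(spec)
  tracks <- simulate_tracks(spec, sim$truth)
  list(spec = spec, truth = sim$truth, matrix = sim$matrix,
       peaks = tracks$peaks, genes = tracks$genes)
}

#' Write a simulated genome to a directory
#'
#' Writes the triplet matrix + bin table, one BED per mark, the gene TSV and
#' a `ground_truth.json` with the planted structure.
#'
#' @param sim result of [simulate_genome()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_synthetic_genome <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_bin_table(sim$matrix$bins, file.path(outdir, "bins.tsv"))
  write_contact_matrix(sim$matrix, file.path(outdir, "matrix.tsv"))
  for (mark in names(sim$peaks)) {
    df <- sim$peaks[[mark]]
    write_bed(df[, c("chrom", "start", "end", "name", "signal")],
              file.path(outdir, paste0(mark, ".bed")))
  }
  write_genes(sim$genes, file.path(outdir, "genes.tsv"))
  tr <- sim$truth
  gt <- list(compartment = tr$compartment,
             boundaries = tr$boundaries,
             tads = tr$tads[, c("chrom", "start", "end", "label")],
             loops = tr$loops[, c("chrom", "lbin1", "lbin2", "bin1", "bin2", "class")],
             elements = tr$elements,
             gene_tiers = tr$genes[, c("gene_id", "tier", "role")])
  jsonlite::write_json(gt, file.path(outdir, "ground_truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
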