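# quadratic brute-force overlap oracle: does interval [s1,e1) touch [s2,e2)?
touches <- function(c1, s1, e1, c2, s2, e2) c1 == c2 & s1 < e2 & s2 < e1

# brute-force anchor labelling against a region set
brute_hits <- function(loops, side, regions) {
  if (is.null(regions) || nrow(regions) == 0) return(rep(FALSE, nrow(loops)))
  ch <- loops[[paste0("chrom", side)]]
  st <- loops[[paste0("start", side)]]
  en <- loops[[paste0("end", side)]]
  vapply(seq_len(nrow(loops)), function(i)
    any(touches(ch[i], st[i], en[i], regions$chrom, regions$start,
                regions$end)), TRUE)
}

# shared fixture: annotate the planted loops of the seed-1 genome with the
# recovered element sets
annotated_fixture <- local({
  memo <- NULL
  function() {
    if (!is.null(memo)) return(memo)
    sim <- cached_sim(1)
    pr <- define_promoters(sim$genes)
    k27 <- rank_and_cut(stitch(sim$peaks$H3K27ac), mark = "H3K27ac")
    enh <- define_enhancers(k27, pr)
    k27me3 <- rank_and_cut(stitch(sim$peaks$H3K27me3), mark = "H3K27me3")
    k9 <- rank_and_cut(stitch(sim$peaks$H3K9me2), mark = "H3K9me2")
    sil <- list(SuReR = k27me3[k27me3$super, ], TyReR = k27me3[!k27me3$super, ],
                SuHeR = k9[k9$super, ], TyHeR = k9[!k9$super, ])
    pl <- sim$truth$loops
    loops <- mk_loops(sim$matrix$bins, pl$bin1, pl$bin2)
    ann <- annotate_anchors(loops, enh, pr, sil, sim$peaks$CTCF,
                            sim$peaks$SMC1)
    memo <<- list(sim = sim, pr = pr, enh = enh, sil = sil, ann = ann,
                  truth_class = pl$class)
    memo
  }
})

test_that("anchor labels match the quadratic brute-force oracle", {
  fx <- annotated_fixture()
  ann <- fx$ann
  expect_equal(ann$prom1, brute_hits(ann, 1, fx$pr))
  expect_equal(ann$prom2, brute_hits(ann, 2, fx$pr))
  expect_equal(ann$enh1, brute_hits(ann, 1, fx$enh))
  expect_equal(ann$surer2, brute_hits(ann, 2, fx$sil$SuReR))
  expect_equal(ann$ctcf1, brute_hits(ann, 1, fx$sim$peaks$CTCF))
})

test_that("loop classes recover the planted loop types", {
  fx <- annotated_fixture()
  got <- fx$ann$class
  tc <- fx$truth_class
  expect_true(all(got[tc == "ep"] == "E-P"))
  expect_true(all(got[tc == "se_p"] == "E-P"))
  expect_true(all(got[tc %in% c("ee", "se_se")] == "E-E"))
  expect_true(all(got[tc == "pp"] == "P-P"))
  expect_true(all(got[tc == "ctcf"] == "CTCF-CTCF"))
  expect_true(all(got[tc == "surer_surer"] == "SuReR-SuReR"))
  expect_true(all(got[tc == "suher_suher"] == "SuHeR-SuHeR"))
  # every loop has exactly one class: counts partition the set
  expect_equal(sum(table(got)), nrow(fx$ann))
})

test_that("the precedence ladder resolves dual-label anchors", {
  bins <- make_bins(c(chr1 = 1e6), 1e4)
  loops <- mk_loops(bins, c(10L, 30L), c(20L, 40L))
  enh <- data.frame(chrom = "chr1", start = c(95000, 190000), end = c(98000, 195000),
                    element = 1:2, super = FALSE, class = "TE")
  pr <- data.frame(chrom = "chr1", start = 96000, end = 99000,
                   gene_id = "g1", tss = 97000, tpm = 5)
  ctcf <- mk_peaks("chr1", c(295000, 395000), c(296000, 396000))
  ann <- annotate_anchors(loops, enh, pr, list(), ctcf, NULL)
  # anchor 1 of loop 1 overlaps enhancer AND promoter; partner an enhancer
  expect_true(ann$enh1[1] && ann$prom1[1] && ann$enh2[1])
  expect_equal(ann$class[1], "E-P")        # promoter precedence
  # CTCF-CTCF only without enhancer/promoter labels
  expect_equal(ann$class[2], "CTCF-CTCF")
  expect_equal(ann$occupancy[2], "CTCF only")
  ann2 <- annotate_anchors(loops, enh, pr, list(), ctcf, ctcf)
  expect_equal(ann2$occupancy[2], "CTCF&SMC1")
})

test_that("expression tiers honor the exact TPM boundaries", {
  expect_equal(expression_tier(c(10, 0.1, 0.0999, 200, 9.9999, 0)),
               c("high", "low", "none", "high", "low", "none"))
  expect_error(expression_tier(-1), "negative")
  grid <- c(0, 0.0999999, 0.1, 0.1000001, 1, 9.999999, 10, 10.000001, 1e4)
  tiers <- expression_tier(grid)
  expect_equal(tiers, ifelse(grid >= 10, "high",
                             ifelse(grid >= 0.1, "low", "none")))
})

test_that("promoter-pair fold changes follow the pseudocount arithmetic", {
  bins <- make_bins(c(chr1 = 1e6), 1e4)
  loops <- mk_loops(bins, c(10L, 30L, 50L), c(20L, 40L, 60L))
  pr <- data.frame(chrom = "chr1",
                   start = c(91000, 191000, 291000, 391000, 491000, 591000),
                   end = c(94000, 194000, 294000, 394000, 494000, 594000),
                   gene_id = paste0("g", 1:6),
                   tss = c(92000, 192000, 292000, 392000, 492000, 592000),
                   tpm = c(20, 5, 0, 0, 50, 0))
  ann <- annotate_anchors(loops, NULL, pr, list(), NULL, NULL)
  expect_true(all(ann$class == "P-P"))
  fc <- pp_fold_changes(ann, pr, pseudocount = 0.01)
  expect_equal(fc$pairs$fold, c(20.01 / 5.01, 1, 50.01 / 0.01),
               tolerance = 1e-12)
  expect_equal(fc$frac_gt2, 2 / 3)         # folds ~3.99 and 5001
  expect_equal(fc$frac_gt10, 1 / 3)        # only the 5001-fold pair
  expect_equal(fc$pairs$gene_high[3], "g5")
})

test_that("anchors without genes drop the pair and are counted", {
  bins <- make_bins(c(chr1 = 1e6), 1e4)
  loops <- mk_loops(bins, 10L, 20L)
  pr <- data.frame(chrom = "chr1", start = 101000, end = 104000,
                   gene_id = "g1", tss = 102000, tpm = 3)
  ann <- annotate_anchors(loops, NULL, pr, list(), NULL, NULL)
  ann$class <- "P-P"   # force the class despite the one-sided promoter
  fc <- pp_fold_changes(ann, pr)
  expect_equal(fc$n_pairs, 0)
  expect_equal(fc$n_dropped, 1)
})

test_that("occupancy patterns partition every loop set", {
  fx <- annotated_fixture()
  frac <- occupancy_pattern(fx$ann)
  expect_true(all(abs(rowSums(frac) - 1) < 1e-12))
  ctcf_rows <- fx$ann$class == "CTCF-CTCF"
  expect_true(all(fx$ann$occupancy[ctcf_rows] == "CTCF&SMC1"))
})

test_that("interaction density normalizes per unit length", {
  bins <- make_bins(c(chr1 = 2e6), 1e4)
  region <- data.frame(chrom = "chr1", start = 1e5, end = 3e5)  # 200 kb
  loops <- mk_loops(bins, c(12L, 15L, 18L, 25L), c(80L, 90L, 100L, 110L))
  expect_equal(interaction_density(region, loops), 4 * 1e5 / 2e5)
  none <- data.frame(chrom = "chr1", start = 1.5e6, end = 1.6e6)
  expect_equal(interaction_density(none, loops), 0)
  expect_error(interaction_density(data.frame(chrom = "chr1", start = 5,
                                              end = 5), loops), "zero-length")
})

test_that("interaction density equals a brute-force count on nested regions", {
  withr::local_seed(19)
  bins <- make_bins(c(chr1 = 5e6), 1e4)
  b1 <- sample.int(200, 60); b2 <- b1 + sample(5:200, 60, TRUE)
  loops <- mk_loops(bins, b1, pmin(b2, 500L))
  regions <- data.frame(chrom = "chr1",
                        start = c(0, 0, 5e5, 1e6, 1.2e6),
                        end = c(2e6, 1e6, 1.5e6, 1.4e6, 1.25e6))
  got <- interaction_density(regions, loops, per_bp = 1e5)
  for (r in seq_len(nrow(regions))) {
    cnt <- sum(touches(loops$chrom1, loops$start1, loops$end1, regions$chrom[r],
                       regions$start[r], regions$end[r]) |
               touches(loops$chrom2, loops$start2, loops$end2, regions$chrom[r],
                       regions$start[r], regions$end[r]))
    expect_equal(got[r], cnt * 1e5 / (regions$end[r] - regions$start[r]))
  }
})

test_that("genes looped to regions match the brute-force oracle", {
  fx <- annotated_fixture()
  ann <- fx$ann; pr <- fx$pr
  for (set in c("SuReR", "SuHeR")) {
    got <- genes_looped_to(fx$sil[[set]], ann, pr)
    # oracle: double loop over loops x promoters
    want <- character(0)
    for (i in seq_len(nrow(ann))) {
      r1 <- brute_hits(ann[i, ], 1, fx$sil[[set]])
      r2 <- brute_hits(ann[i, ], 2, fx$sil[[set]])
      for (j in seq_len(nrow(pr))) {
        p1 <- touches(ann$chrom1[i], ann$start1[i], ann$end1[i],
                      pr$chrom[j], pr$start[j], pr$end[j])
        p2 <- touches(ann$chrom2[i], ann$start2[i], ann$end2[i],
                      pr$chrom[j], pr$start[j], pr$end[j])
        if ((p1 && r2) || (p2 && r1)) want <- c(want, pr$gene_id[j])
      }
    }
    expect_equal(got, sort(unique(want)))
    expect_gte(length(got), 1)   # the planted silencer-looped genes
  }
  # a loop with both anchors inside the region set contributes no gene
  bins <- make_bins(c(chr1 = 1e6), 1e4)
  lp <- mk_loops(bins, 10L, 30L)
  reg <- data.frame(chrom = "chr1", start = c(95000, 295000),
                    end = c(105000, 305000))
  pr2 <- data.frame(chrom = "chr1", start = 7e5, end = 7.1e5,
                    gene_id = "g", tss = 7e5 + 100, tpm = 1)
  expect_equal(genes_looped_to(reg, lp, pr2), character(0))
})

test_that("silencer-looped genes are silent in the planted genome", {
  fx <- annotated_fixture()
  genes <- fx$sim$genes
  looped <- genes_looped_to(fx$sil$SuReR, fx$ann, fx$pr)
  expect_true(all(genes$tier[genes$gene_id %in% looped] == "none"))
})

test_that("E-P containment inside CTCF-CTCF domains", {
  bins <- make_bins(c(chr1 = 2e6), 1e4)
  ctcf <- mk_loops(bins, 10L, 60L)        # domain spans bins 10..60
  inside <- mk_loops(bins, 20L, 40L)
  straddle <- mk_loops(bins, 40L, 80L)
  res <- containment_in_ctcf_domains(rbind(inside, straddle), ctcf)
  expect_equal(res$contained, c(TRUE, FALSE))
  expect_equal(res$fraction, 0.5)
  # anchors of the domain count as inside
  at_edge <- mk_loops(bins, 10L, 60L)
  expect_true(containment_in_ctcf_domains(at_edge, ctcf)$contained)
  # planted genome: all planted E/P loops sit inside planted CTCF domains
  fx <- annotated_fixture()
  ep <- fx$ann[fx$ann$class == "E-P", ]
  cc <- fx$ann[fx$ann$class == "CTCF-CTCF", ]
  expect_gte(containment_in_ctcf_domains(ep, cc)$fraction, 0.9)
})

test_that("loop lengths use anchor starts and order by class as planted", {
  bins <- make_bins(c(chr1 = 1e6), 1e4)
  lp <- mk_loops(bins, c(11L, 5L), c(37L, 10L))
  lp$class <- c("E-P", "E-P")
  lp2 <- mk_loops(bins, 3L, 20L, trans = TRUE)
  lp2$class <- "E-P"
  st <- loop_length_stats(rbind(lp, lp2))
  expect_equal(st$stats$median[st$stats$class == "E-P"],
               median(c(260000, 50000)))
  expect_equal(st$n_trans_excluded, 1)
  st1 <- loop_length_stats(lp[1, ])
  expect_equal(st1$stats$median, 260000)
  # planted genome: CTCF-CTCF loops are longer than E-P loops
  fx <- annotated_fixture()
  st <- loop_length_stats(fx$ann)$stats
  expect_gt(st$median[st$class == "CTCF-CTCF"], st$median[st$class == "E-P"])
})
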