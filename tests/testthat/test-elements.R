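# independent union-find oracle for transitive stitching
uf_stitch <- function(peaks, gap) {
  n <- nrow(peaks)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || peaks$chrom[i] != peaks$chrom[j]) next
    g <- max(peaks$start[i], peaks$start[j]) - min(peaks$end[i], peaks$end[j])
    if (g <= gap) parent[find(i)] <- find(j)
  }
  vapply(seq_len(n), find, 0L)
}

# independent slope-scan oracle for the ROSE cutoff
rose_oracle_super <- function(signal) {
  n <- length(signal)
  s <- sort(signal)
  xs <- (seq_len(n) - 1) / (n - 1)
  ys <- (s - s[1]) / (s[n] - s[1])
  j <- NA
  for (k in seq_len(n - 1))
    if ((ys[k + 1] - ys[k]) / (xs[k + 1] - xs[k]) > 1) { j <- k; break }
  if (is.na(j)) return(rep(FALSE, n))
  signal > s[j]
}

test_that("stitching merges at the threshold gap, strictly", {
  p <- mk_peaks("chr1", c(0, 13000), c(1000, 14000))
  st <- stitch(p, 12500)                   # gap 12000 <= 12500
  expect_equal(nrow(st), 1)
  expect_equal(c(st$start, st$end), c(0, 14000))
  p2 <- mk_peaks("chr1", c(0, 13501), c(1000, 14000))   # gap 12501
  expect_equal(nrow(stitch(p2, 12500)), 2)
  expect_error(stitch(p, -1), "non-negative")
})

test_that("stitching is transitive and matches a union-find oracle", {
  p <- mk_peaks("chr1", seq(0, 4) * 11000, seq(0, 4) * 11000 + 1000)
  st <- stitch(p, 12500)                   # chain of 5, 10-kb gaps
  expect_equal(nrow(st), 1)
  expect_equal(st$n_constituents, 5)

  withr::local_seed(15)
  for (rep in 1:5) {
    p <- mk_peaks(sample(c("chr1", "chr2"), 40, TRUE),
                  sample.int(5e5, 40), 0, signal = runif(40, 1, 5))
    p$end <- p$start + sample.int(2e4, 40)
    st <- stitch(p, 12500)
    oracle <- uf_stitch(p, 12500)
    expect_equal(nrow(st), length(unique(oracle)))
    got <- attr(st, "constituent_of")
    expect_equal(length(unique(paste(got, oracle))), length(unique(oracle)))
    # stitched output is pairwise disjoint with gaps above the threshold
    for (ch in unique(st$chrom)) {
      s <- st[st$chrom == ch, ]
      s <- s[order(s$start), ]
      if (nrow(s) > 1) expect_true(all(s$start[-1] - s$end[-nrow(s)] > 12500))
    }
  }
})

test_that("aggregate signal is density times length summed over constituents", {
  p <- mk_peaks("chr1", c(0, 2000), c(1000, 5000), signal = c(2, 10))
  st <- stitch(p, 12500)
  expect_equal(st$signal, 2 * 1000 + 10 * 3000)
})

test_that("the ROSE cutoff matches the brute-force slope scan", {
  st <- data.frame(chrom = "chr1", start = 1:5 * 1e4, end = 1:5 * 1e4 + 100,
                   n_constituents = 1, signal = c(1, 1, 1, 1, 100),
                   element = 1:5)
  rc <- rank_and_cut(st)
  expect_equal(rc$super, rose_oracle_super(st$signal))
  expect_equal(sum(rc$super), 1)
  expect_true(rc$super[rc$signal == 100])

  st$signal <- 2^(0:4) * 10
  geo <- data.frame(chrom = "chr1", start = 1:10 * 1e4,
                    end = 1:10 * 1e4 + 100, n_constituents = 1,
                    signal = 2^(0:9), element = 1:10)
  rcg <- rank_and_cut(geo)
  expect_equal(rcg$super, rose_oracle_super(geo$signal))

  withr::local_seed(16)
  for (rep in 1:10) {
    sig <- exp(rnorm(30, 2, 1.5))
    df <- data.frame(chrom = "chr1", start = 1:30, end = 1:30 + 1,
                     n_constituents = 1, signal = sig, element = 1:30)
    expect_equal(rank_and_cut(df)$super, rose_oracle_super(sig))
  }
})

test_that("degenerate element sets are all typical", {
  eq <- data.frame(chrom = "chr1", start = 1:5, end = 2:6,
                   n_constituents = 1, signal = rep(3, 5), element = 1:5)
  expect_false(any(rank_and_cut(eq)$super))
  two <- eq[1:2, ]
  expect_warning(rc <- rank_and_cut(two), "fewer than 3")
  expect_false(any(rc$super))
})

test_that("adding a zero-signal element never demotes a super element", {
  withr::local_seed(17)
  for (rep in 1:20) {
    sig <- c(exp(rnorm(15, 1, 1)), exp(rnorm(3, 5, 0.3)))
    df <- data.frame(chrom = "chr1", start = seq_along(sig),
                     end = seq_along(sig) + 1, n_constituents = 1,
                     signal = sig, element = seq_along(sig))
    before <- df$signal[rank_and_cut(df)$super]
    df0 <- rbind(df, transform(df[1, ], signal = 0, element = 99))
    after <- df0$signal[rank_and_cut(df0)$super]
    expect_true(all(before %in% after))
  }
})

test_that("rank is a permutation with 1 as the highest signal", {
  withr::local_seed(18)
  sig <- runif(12, 0, 100)
  df <- data.frame(chrom = "chr1", start = 1:12, end = 2:13,
                   n_constituents = 1, signal = sig, element = 1:12)
  rc <- rank_and_cut(df)
  expect_setequal(rc$rank, 1:12)
  expect_equal(rc$signal[rc$rank == 1], max(sig))
})

test_that("promoters are TSS +/- flank with strand arithmetic and clipping", {
  g <- data.frame(chrom = "chr1", start = c(10000, 10000, 500),
                  end = c(20000, 20000, 4000), strand = c("+", "-", "+"),
                  gene_id = c("a", "b", "c"))
  pr <- define_promoters(g, flank = 2000)
  expect_equal(c(pr$start[1], pr$end[1]), c(8000, 12000))
  # minus strand: TSS = end - 1 = 19999
  expect_equal(pr$tss[2], 19999)
  expect_equal(c(pr$start[2], pr$end[2]), c(17999, 22000))
  expect_equal(pr$start[3], 0)                       # clipped at chrom start
  expect_true(all(pr$start <= pr$tss & pr$tss < pr$end))
})

test_that("enhancers are exactly the promoter-free H3K27ac elements", {
  el <- data.frame(chrom = "chr1", start = c(0, 50000), end = c(1000, 51000),
                   n_constituents = 1, signal = c(5, 5), element = 1:2,
                   super = FALSE, class = "TE")
  pr <- data.frame(chrom = "chr1", start = 50999, end = 53000,
                   gene_id = "g", tss = 51500)
  enh <- define_enhancers(el, pr)                    # 1-bp overlap excluded
  expect_equal(enh$element, 1)
  pr2 <- transform(pr, start = 51000)
  expect_equal(define_enhancers(el, pr2)$element, 1:2)
})

test_that("planted super elements are recovered with high interval overlap", {
  sim <- cached_sim(1)
  pr <- define_promoters(sim$genes)
  for (mk in c("H3K27ac", "H3K27me3", "H3K9me2")) {
    cls <- rank_and_cut(stitch(sim$peaks[[mk]]), mark = mk)
    sup <- cls[cls$super, ]
    typ <- cls[!cls$super, ]
    truth_cls <- switch(mk, H3K27ac = "SE", H3K27me3 = "SuReR",
                        H3K9me2 = "SuHeR")
    planted <- truth_elements(sim$truth, truth_cls)
    expect_equal(nrow(sup), nrow(planted))
    expect_gte(interval_jaccard(sup, planted), 0.9)
    # super elements are longer than typical ones (hockey-stick geometry)
    expect_gt(median(sup$end - sup$start), median(typ$end - typ$start))
  }
  enh <- define_enhancers(rank_and_cut(stitch(sim$peaks$H3K27ac),
                                       mark = "H3K27ac"), pr)
  se <- enh[enh$super, ]
  expect_gte(interval_jaccard(se, truth_elements(sim$truth, "SE")), 0.9)
})

test_that("silencer overlap fractions are counted per element set", {
  a <- data.frame(chrom = "chr1", start = c(0, 1e5, 2e5) * 10,
                  end = c(0, 1e5, 2e5) * 10 + 5e4)
  b <- transform(a, start = start + 5e6, end = end + 5e6)
  expect_equal(silencer_overlap_fraction(a, b), c(surer = 0, suher = 0))
  expect_equal(silencer_overlap_fraction(a, a), c(surer = 1, suher = 1))
  ten <- data.frame(chrom = "chr1", start = (0:9) * 1e5, end = (0:9) * 1e5 + 100)
  two <- ten[1:2, ]
  expect_equal(silencer_overlap_fraction(ten, two)[["surer"]], 0.2)
  # one planted SuReR/SuHeR overlap per odd chromosome in the simulation
  sim <- cached_sim(1)
  fr <- silencer_overlap_fraction(truth_elements(sim$truth, "SuReR"),
                                  truth_elements(sim$truth, "SuHeR"))
  expect_gt(fr[["surer"]], 0)
  expect_lt(fr[["surer"]], 0.5)
})
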