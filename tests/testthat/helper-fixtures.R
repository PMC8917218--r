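# Shared fixtures. Simulated genomes are expensive (a few seconds each), so
# they are memoised for the whole test session.

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(seed, ...) {
  key <- paste0("s", seed, "_", paste(deparse(list(...)), collapse = ""))
  key <- gsub("[^a-zA-Z0-9]", "", key)
  if (!exists(key, .sim_cache))
    assign(key, simulate_genome(synthetic_spec(seed = seed, ...)), .sim_cache)
  get(key, .sim_cache)
}

# small 2 x 10 Mb genome: same planted layout, ~4x faster
small_spec <- function(seed, ...) {
  synthetic_spec(chrom_lengths = c(chr1 = 10e6, chr2 = 10e6),
                 n_genes = 250, seed = seed, ...)
}

cached_small_sim <- function(seed, ...) {
  key <- paste0("sm", seed, "_", paste(deparse(list(...)), collapse = ""))
  key <- gsub("[^a-zA-Z0-9]", "", key)
  if (!exists(key, .sim_cache))
    assign(key, simulate_genome(small_spec(seed = seed, ...)), .sim_cache)
  get(key, .sim_cache)
}

# contact_matrix from a dense symmetric matrix on one or two toy chromosomes
cm_from_dense <- function(d, binwidth = 1e4, chrom = "chrX", gc = 0.4,
                          mask = NULL, balanced = FALSE) {
  n <- nrow(d)
  bins <- make_bins(stats::setNames(n * binwidth, chrom), binwidth, gc = gc)
  idx <- which(upper.tri(d, diag = TRUE), arr.ind = TRUE)
  cnt <- data.frame(bin1 = idx[, 1], bin2 = idx[, 2], count = d[idx])
  contact_matrix(bins, cnt[cnt$count != 0, ], mask = mask,
                 balanced = balanced)
}

dense_from_cm <- function(cm) {
  n <- n_bins(cm)
  d <- matrix(0, n, n)
  d[cbind(cm$counts$bin1, cm$counts$bin2)] <- cm$counts$count
  d[cbind(cm$counts$bin2, cm$counts$bin1)] <- cm$counts$count
  d
}

# map planted element truth intervals of one class to a data.frame
truth_elements <- function(truth, cls) {
  el <- truth$elements[truth$elements$class == cls, , drop = FALSE]
  rownames(el) <- NULL
  el
}

# interval-set Jaccard (bp of intersection / bp of union) via GRanges
interval_jaccard <- function(a, b) {
  ga <- GenomicRanges::reduce(GenomicRanges::GRanges(
    a$chrom, IRanges::IRanges(a$start + 1L, a$end)))
  gb <- GenomicRanges::reduce(GenomicRanges::GRanges(
    b$chrom, IRanges::IRanges(b$start + 1L, b$end)))
  inter <- sum(IRanges::width(GenomicRanges::intersect(ga, gb)))
  uni <- sum(IRanges::width(GenomicRanges::union(ga, gb)))
  inter / uni
}

# peaks data.frame shortcut
mk_peaks <- function(chrom, start, end, signal = 1) {
  data.frame(chrom = chrom, start = start, end = end, signal = signal,
             stringsAsFactors = FALSE)
}

# minimal loop frame from anchor bins on a bin table
mk_loops <- function(bins, bin1, bin2, trans = FALSE) {
  data.frame(chrom1 = bins$chrom[bin1], start1 = bins$start[bin1],
             end1 = bins$end[bin1], chrom2 = bins$chrom[bin2],
             start2 = bins$start[bin2], end2 = bins$end[bin2],
             bin1 = bin1, bin2 = bin2, count = 10, prob = 1e-9,
             pval = 1e-9, qval = 1e-9,
             trans = rep_len(trans, length(bin1)),
             stringsAsFactors = FALSE)
}

# standard end-to-end input list for run_all() from a written genome dir
genome_inputs <- function(dir) {
  marks <- c("H3K27ac", "H3K27me3", "H3K9me2", "H3K4me3", "CTCF", "SMC1")
  list(bins = file.path(dir, "bins.tsv"),
       matrix = file.path(dir, "matrix.tsv"),
       genes = file.path(dir, "genes.tsv"),
       peaks = as.list(stats::setNames(file.path(dir, paste0(marks, ".bed")),
                                       marks)))
}
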