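#' @title File formats
#' @description
#' All text formats are tab-separated; lines starting with `#` are ignored.
#' Coordinates are 0-based half-open throughout (the BED convention); no
#' 1-based format is read or written. Chromosome names are compared by exact
#' string match. Triplet matrix files use 0-based global bin indices.
#' @name io_formats
NULL

read_tsv_lines <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

stop_line <- function(path, lineno, msg) {
  stop(sprintf("%s: line %d: %s", path, lineno, msg), call. = FALSE)
}

#' Read a BED file of peaks
#'
#' Accepts 3+ column BED; column 4 is a name and column 5 a signal score.
#' A missing score is read as signal 0. Malformed lines (non-integer
#' coordinates, `end <= start`) are rejected with their line number.
#'
#' @param path BED file path.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `signal`.
#' @export
read_bed <- function(path) {
  tl <- read_tsv_lines(path)
  if (length(tl$lines) == 0)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), signal = numeric()))
  fields <- strsplit(tl$lines, "\t", fixed = TRUE)
  out <- vector("list", length(fields))
  for (k in seq_along(fields)) {
    f <- fields[[k]]
    if (length(f) < 3) stop_line(path, tl$lineno[k], "fewer than 3 columns")
    start <- suppressWarnings(as.numeric(f[2])); end <- suppressWarnings(as.numeric(f[3]))
    if (is.na(start) || is.na(end) || start != floor(start) || end != floor(end))
      stop_line(path, tl$lineno[k], "non-integer coordinates")
    if (end <= start || start < 0)
      stop_line(path, tl$lineno[k], sprintf("invalid interval [%s, %s)", f[2], f[3]))
    sig <- if (length(f) >= 5) suppressWarnings(as.numeric(f[5])) else 0
    if (is.na(sig)) stop_line(path, tl$lineno[k], "non-numeric score")
    out[[k]] <- list(chrom = f[1], start = start, end = end,
                     name = if (length(f) >= 4) f[4] else NA_character_,
                     signal = sig)
  }
  data.frame(chrom = vapply(out, `[[`, "", "chrom"),
             start = vapply(out, `[[`, 0, "start"),
             end = vapply(out, `[[`, 0, "end"),
             name = vapply(out, `[[`, "", "name"),
             signal = vapply(out, `[[`, 0, "signal"),
             stringsAsFactors = FALSE)
}

#' Write intervals as BED
#'
#' Writes `chrom`, `start`, `end`, plus `name` and a score column when
#' present (`signal` or `score`). Round-trips with [read_bed()] exactly for
#' coordinates and scores. An empty input yields an empty file.
#'
#' @param x `data.frame` of intervals.
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  if (nrow(x) == 0) { cat("", file = path); return(invisible(path)) }
  score <- if ("signal" %in% names(x)) x$signal else x$score
  name <- if ("name" %in% names(x) && !all(is.na(x$name))) x$name else NULL
  cols <- list(x$chrom, format_int(x$start), format_int(x$end))
  if (!is.null(score)) {
    cols <- c(cols, list(if (is.null(name)) rep(".", nrow(x)) else name,
                         format_num(score)))
  } else if (!is.null(name)) {
    cols <- c(cols, list(name))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

format_int <- function(x) format(x, scientific = FALSE, trim = TRUE)
format_num <- function(x) {
  out <- vapply(x, function(v) format(v, scientific = FALSE, trim = TRUE,
                                      digits = 15),
                "")
  out
}

#' Read a gene table
#'
#' Expects a header line `chrom start end strand gene_id tpm` (tab
#' separated). The transcription start site is `start` on the `+` strand and
#' `end - 1` on the `-` strand.
#'
#' @param path TSV path.
#' @return `data.frame` with the six columns plus derived `tss`.
#' @export
read_genes <- function(path) {
  g <- utils::read.table(path, header = TRUE, sep = "\t",
                         comment.char = "#", stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "strand", "gene_id", "tpm")
  if (!all(need %in% names(g)))
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  if (any(g$tpm < 0)) stop("negative TPM in gene table")
  if (any(!g$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  g$tss <- ifelse(g$strand == "+", g$start, g$end - 1L)
  g
}

#' Write a gene table
#' @param genes gene `data.frame` (columns `chrom`, `start`, `end`,
#'   `strand`, `gene_id`, `tpm`).
#' @param path output path.
#' @export
write_genes <- function(genes, path) {
  utils::write.table(genes[, c("chrom", "start", "end", "strand", "gene_id", "tpm")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a bin table
#'
#' Header `chrom start end gc`; bins must tile each chromosome contiguously.
#'
#' @param path TSV path.
#' @param binwidth declared bin width; inferred (modal width) if missing.
#' @return validated bin table.
#' @export
read_bin_table <- function(path, binwidth = NULL) {
  b <- utils::read.table(path, header = TRUE, sep = "\t",
                         comment.char = "#", stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "gc")
  if (!all(need %in% names(b)))
    stop("bin table must have columns: ", paste(need, collapse = ", "))
  b <- validate_bins(b, binwidth)
  b
}

#' Write a bin table
#' @param bins bin table.
#' @param path output path.
#' @export
write_bin_table <- function(bins, path) {
  utils::write.table(bins[, c("chrom", "start", "end", "gc")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sparse triplet contact matrix
#'
#' Triplet lines are `bin1 bin2 count` with 0-based global bin indices
#' (header line required). `(i,j)` and `(j,i)` entries, and duplicates, are
#' folded into a single upper-triangular entry by summation. Negative counts
#' and out-of-range indices are rejected.
#'
#' @param triplet_path triplet TSV path.
#' @param bins_path bin table TSV path.
#' @param balanced whether values are balanced reals rather than raw counts.
#' @return a [contact_matrix()].
#' @export
read_contact_matrix <- function(triplet_path, bins_path, balanced = FALSE) {
  bins <- read_bin_table(bins_path)
  t <- utils::read.table(triplet_path, header = TRUE, sep = "\t",
                         comment.char = "#", stringsAsFactors = FALSE)
  need <- c("bin1", "bin2", "count")
  if (!all(need %in% names(t)))
    stop("triplet file must have columns: ", paste(need, collapse = ", "))
  if (any(t$count < 0)) stop("negative counts in ", triplet_path)
  n <- nrow(bins)
  if (nrow(t) > 0 && (any(t$bin1 < 0 | t$bin1 >= n | t$bin2 < 0 | t$bin2 >= n)))
    stop("bin index out of range in ", triplet_path, " (", n, " bins)")
  contact_matrix(bins,
                 data.frame(bin1 = t$bin1 + 1L, bin2 = t$bin2 + 1L,
                            count = t$count),
                 balanced = balanced)
}

#' Write a contact matrix as sparse triplets
#'
#' Upper-triangular entries with 0-based global bin indices, header
#' `bin1 bin2 count`.
#'
#' @param cm a `contact_matrix`.
#' @param path output path.
#' @export
write_contact_matrix <- function(cm, path) {
  out <- data.frame(bin1 = cm$counts$bin1 - 1L, bin2 = cm$counts$bin2 - 1L,
                    count = cm$counts$count)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write loops as BEDPE
#'
#' Columns: `chrom1 start1 end1 chrom2 start2 end2 count q` with the
#' q-value in column 8; extra annotation columns are appended when present.
#'
#' @param loops loop `data.frame` (from [call_cis_loops()] et al.).
#' @param path output path.
#' @export
write_bedpe <- function(loops, path) {
  if (nrow(loops) == 0) { cat("", file = path); return(invisible(path)) }
  cols <- list(loops$chrom1, format_int(loops$start1), format_int(loops$end1),
               loops$chrom2, format_int(loops$start2), format_int(loops$end2),
               format_num(loops$count), format_num(loops$qval))
  if ("class" %in% names(loops)) cols <- c(cols, list(as.character(loops$class)))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read loops from BEDPE
#' @param path BEDPE path (as written by [write_bedpe()]).
#' @return loop `data.frame`.
#' @export
read_bedpe <- function(path) {
  tl <- read_tsv_lines(path)
  if (length(tl$lines) == 0)
    return(data.frame(chrom1 = character(), start1 = integer(), end1 = integer(),
                      chrom2 = character(), start2 = integer(), end2 = integer(),
                      count = numeric(), qval = numeric()))
  f <- strsplit(tl$lines, "\t", fixed = TRUE)
  bad <- which(vapply(f, length, 0L) < 8)
  if (length(bad))
    stop_line(path, tl$lineno[bad[1]], "BEDPE line has fewer than 8 columns")
  m <- do.call(rbind, f)
  out <- data.frame(chrom1 = m[, 1], start1 = as.integer(m[, 2]),
                    end1 = as.integer(m[, 3]), chrom2 = m[, 4],
                    start2 = as.integer(m[, 5]), end2 = as.integer(m[, 6]),
                    count = as.numeric(m[, 7]), qval = as.numeric(m[, 8]),
                    stringsAsFactors = FALSE)
  if (ncol(m) >= 9) out$class <- m[, 9]
  out
}
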