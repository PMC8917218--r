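#' Default pipeline configuration
#'
#' Returns the full parameter set of the analysis pipeline with the
#' standard defaults: loop calling at the base (10-kb) resolution with the
#' significance filters p < 0.01, q < 0.01, count > 2; insulation/TAD
#' calling at 40 kb with a 480-kb window and 120-kb delta; compartments at
#' 100 kb; ROSE stitching at 12.5 kb; 2-kb promoter flank; 0.01 TPM
#' pseudocount. Resolutions must be multiples of the input bin width.
#' Values can be overridden by a named list or loaded from a YAML file via
#' [read_config()].
#'
#' @param ... overrides (named scalars).
#' @return named list of parameters.
#' @export
default_config <- function(...) {
  cfg <- list(
    compartment_binwidth = 100e3,
    tad_binwidth = 40e3,
    loop_binwidth = 10e3,
    insulation_window = 480e3,
    insulation_delta = 120e3,
    boundary_min_strength = 0.1,
    mask_min_fraction = 0.02,
    ice_max_iter = 200,
    ice_tol = 1e-5,
    loop_p_cut = 0.01,
    loop_q_cut = 0.01,
    loop_min_count_gt = 2,
    loop_min_dist_bins = 2,
    loop_n_strata = 100,
    loop_use_bias = FALSE,
    stitch_distance = 12500,
    promoter_flank = 2000,
    tpm_pseudocount = 0.01,
    repressive_min_coverage = 0.5,
    density_per_bp = 1e5)
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop("unknown config key: ", nm)
    cfg[[nm]] <- over[[nm]]
  }
  cfg
}

#' Read a YAML pipeline configuration
#' @param path YAML file; keys as in [default_config()].
#' @return full config list (unknown keys are an error).
#' @export
read_config <- function(path) {
  default_config(yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Stage order: balance, compartments, domains, loops, elements,
#' annotation, networks. Inputs are the file formats of the io module; all
#' outputs (BED/bedGraph/BEDPE/TSV and a `summary.json` aggregating every
#' fraction and median computed) are written under `outdir`, together with
#' the effective configuration (`config.yaml`). The run is deterministic:
#' rerunning on the same inputs and config reproduces `summary.json`
#' byte-identically.
#'
#' @param inputs named list of paths: `bins`, `matrix`, `genes`, and
#'   `peaks` (a named list of BED paths by mark; `H3K27ac`, `H3K27me3`,
#'   `H3K9me2`, `CTCF`, `SMC1` are used where present).
#' @param outdir output directory.
#' @param config from [default_config()].
#' @return (invisibly) list with all stage results and the summary.
#' @export
run_all <- function(inputs, outdir, config = default_config()) {
  need <- c(inputs$bins, inputs$matrix, inputs$genes, unlist(inputs$peaks))
  missing <- need[!file.exists(need)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(config, file.path(outdir, "config.yaml"))
  log_path <- file.path(outdir, "run.log")
  logf <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    cat(line, "\n", sep = "", file = log_path, append = TRUE)
  }

  cm <- read_contact_matrix(inputs$matrix, inputs$bins)
  for (r in c("compartment_binwidth", "tad_binwidth", "loop_binwidth"))
    if (config[[r]] %% cm$binwidth != 0)
      stop(r, " is not a multiple of the matrix bin width")
  genes <- read_genes(inputs$genes)
  peaks <- lapply(inputs$peaks, read_bed)
  logf("inputs: %d bins, %d stored pairs, %d genes", n_bins(cm),
       nrow(cm$counts), nrow(genes))

  # --- balance at loop resolution ---
  cml <- coarsen(cm, config$loop_binwidth)
  cml <- mask_low_coverage(cml, config$mask_min_fraction)
  bal <- ice_balance(cml, config$ice_max_iter, config$ice_tol)
  if (!bal$converged) logf("WARN: ICE did not converge at loop resolution")
  utils::write.table(data.frame(bin = seq_len(n_bins(cml)) - 1L,
                                bias = bal$bias),
                     file.path(outdir, "bias.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # --- compartments at coarse resolution ---
  cmc <- mask_low_coverage(coarsen(cm, config$compartment_binwidth),
                           config$mask_min_fraction)
  balc <- ice_balance(cmc, config$ice_max_iter, config$ice_tol)
  comp <- call_compartments(balc$matrix)
  write_bedgraph(comp[, c("chrom", "start", "end")], comp$pc1,
                 file.path(outdir, "compartments.bedGraph"))
  segs <- compartment_segments(comp)
  segs$name <- segs$label
  write_bed(segs[, c("chrom", "start", "end", "name")],
            file.path(outdir, "compartments.bed"))
  comp_frac <- compartment_genome_fractions(comp)
  logf("compartments: A %.3f B %.3f NA %.3f", comp_frac[1], comp_frac[2],
       comp_frac[3])

  # --- domains at TAD resolution ---
  cmt <- mask_low_coverage(coarsen(cm, config$tad_binwidth),
                           config$mask_min_fraction)
  balt <- ice_balance(cmt, config$ice_max_iter, config$ice_tol)
  ins <- insulation_score(balt$matrix, config$insulation_window)
  bnd <- call_boundaries(ins, config$insulation_delta,
                         config$boundary_min_strength)
  tads <- tad_set(bnd, balt$matrix$bins)
  write_bedgraph(ins[, c("chrom", "start", "end")], ins$score,
                 file.path(outdir, "insulation.bedGraph"))
  write_bed(transform(tads$boundaries, name = "boundary",
                      signal = strength),
            file.path(outdir, "boundaries.bed"))
  write_bed(tads$domains, file.path(outdir, "tads.bed"))
  logf("domains: %d TADs, median %.0f kb", nrow(tads$domains),
       stats::median(tads$domains$end - tads$domains$start) / 1e3)

  # --- loops at fine resolution ---
  expd <- expected_cis(cml, config$loop_n_strata, config$loop_min_dist_bins)
  loop_bias <- if (config$loop_use_bias) bal$bias else NULL
  cis_loops <- call_cis_loops(cml, expd, loop_bias, config$loop_p_cut,
                              config$loop_q_cut, config$loop_min_count_gt)
  trans_loops <- call_trans_loops(cml, loop_bias, config$loop_p_cut,
                                  config$loop_q_cut, config$loop_min_count_gt)
  loops <- rbind(cis_loops, trans_loops)
  logf("loops: %d cis, %d trans", nrow(cis_loops), nrow(trans_loops))

  # --- stitched elements ---
  stitched <- lapply(stats::setNames(nm = intersect(
    c("H3K27ac", "H3K27me3", "H3K9me2"), names(peaks))), function(mk)
      call_stitched_elements(peaks[[mk]], mk, config$stitch_distance))
  promoters <- define_promoters(genes, config$promoter_flank)
  enhancers <- if ("H3K27ac" %in% names(stitched))
    define_enhancers(stitched$H3K27ac, promoters) else NULL
  silencers <- list(
    SuReR = subset_class(stitched$H3K27me3, TRUE),
    TyReR = subset_class(stitched$H3K27me3, FALSE),
    SuHeR = subset_class(stitched$H3K9me2, TRUE),
    TyHeR = subset_class(stitched$H3K9me2, FALSE))
  for (mk in names(stitched))
    write_bed(transform(stitched[[mk]], name = class),
              file.path(outdir, paste0("elements_", mk, ".bed")))

  # --- annotation ---
  ann <- annotate_anchors(loops, enhancers, promoters, silencers,
                          peaks$CTCF, peaks$SMC1)
  write_bedpe(ann, file.path(outdir, "loops.bedpe"))
  ep <- ann[ann$class == "E-P", , drop = FALSE]
  cc <- ann[ann$class == "CTCF-CTCF", , drop = FALSE]
  contain <- containment_in_ctcf_domains(ep, cc, tads)
  lstats <- loop_length_stats(ann)
  ppfc <- pp_fold_changes(ann, promoters, config$tpm_pseudocount)
  rep_flags <- lapply(stats::setNames(nm = intersect(
    c("H3K27me3", "H3K9me2"), names(peaks))), function(mk)
      flag_repressive_tads(tads, peaks[[mk]], config$repressive_min_coverage))

  # --- networks ---
  hubs <- list()
  if (!is.null(enhancers)) {
    net <- build_ep_network(ann, enhancers, promoters)
    hubs <- find_se_hubs(net)
    edges <- igraph::as_data_frame(net, what = "edges")
    utils::write.table(edges, file.path(outdir, "network_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  class_counts <- as.list(table(ann$class))
  summary <- list(
    n_bins = n_bins(cm),
    compartment_fractions = as.list(comp_frac),
    n_tads = nrow(tads$domains),
    tad_median_bp = stats::median(tads$domains$end - tads$domains$start),
    n_cis_loops = nrow(cis_loops),
    n_trans_loops = nrow(trans_loops),
    intra_tad_fraction = intra_tad_fraction(cis_loops, tads),
    loop_class_counts = class_counts,
    n_enhancers = if (is.null(enhancers)) 0L else nrow(enhancers),
    n_se = if (is.null(enhancers)) 0L else sum(enhancers$super),
    n_surer = nrow(silencers$SuReR %||% data.frame()),
    n_suher = nrow(silencers$SuHeR %||% data.frame()),
    n_repressive_tads = lapply(rep_flags, sum),
    ep_containment_fraction = contain$fraction,
    loop_length_medians = stats::setNames(as.list(lstats$stats$median),
                                          lstats$stats$class),
    pp_frac_gt2 = ppfc$frac_gt2,
    pp_frac_gt10 = ppfc$frac_gt10,
    n_se_hubs = length(hubs))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  logf("summary written")
  invisible(list(matrix = cm, balanced = bal, compartments = comp,
                 insulation = ins, tads = tads, loops = ann,
                 elements = stitched, enhancers = enhancers,
                 promoters = promoters, silencers = silencers,
                 containment = contain, pp = ppfc, hubs = hubs,
                 summary = summary))
}

subset_class <- function(el, super) {
  if (is.null(el)) return(NULL)
  out <- el[el$super == super, , drop = FALSE]
  rownames(out) <- NULL
  out
}

write_bedgraph <- function(intervals, value, path) {
  keep <- !is.na(value)
  writeLines(paste(intervals$chrom[keep], format_int(intervals$start[keep]),
                   format_int(intervals$end[keep]),
                   format_num(value[keep]), sep = "\t"), path)
  invisible(path)
}
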