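#' Build the enhancer-promoter interaction graph
#'
#' One node per distinct enhancer element (typed SE or TE) and per distinct
#' promoter; one edge per interacting pair, built from loops of class E-P,
#' E-E and P-P. Each anchor maps to the overlapped promoter's gene (nearest
#' TSS on ties) when it has a promoter label, otherwise to the overlapped
#' enhancer element (largest overlap on ties). Duplicate loops collapse
#' into one edge with a `multiplicity` attribute.
#'
#' @param annotated annotated loops ([annotate_anchors()]).
#' @param enhancers classified enhancer elements with an `element` id
#'   column.
#' @param promoters promoter set.
#' @return an `igraph` graph; vertex attributes `type` (`"SE"`, `"TE"`,
#'   `"promoter"`) and `name` (`E:<element>` / `P:<gene>`).
#' @export
build_ep_network <- function(annotated, enhancers, promoters) {
  keep <- annotated$class %in% c("E-P", "E-E", "P-P")
  lp <- annotated[keep, , drop = FALSE]
  # map both anchors in one overlap pass
  m <- nrow(lp)
  nodes_both <- anchor_node(c(lp$chrom1, lp$chrom2), c(lp$start1, lp$start2),
                            c(lp$end1, lp$end2), c(lp$prom1, lp$prom2),
                            enhancers, promoters)
  node1 <- nodes_both[seq_len(m)]
  node2 <- nodes_both[m + seq_len(m)]
  ok <- !is.na(node1) & !is.na(node2)
  edges <- data.frame(from = node1[ok], to = node2[ok])
  if (nrow(edges) > 0) {
    key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
    mult <- table(key)
    edges <- edges[!duplicated(key), , drop = FALSE]
    edges$multiplicity <- as.integer(mult[paste(pmin(edges$from, edges$to),
                                                pmax(edges$from, edges$to))])
  } else edges$multiplicity <- integer(0)
  nodes <- unique(c(edges$from, edges$to))
  type <- ifelse(grepl("^P:", nodes), "promoter", NA)
  eid <- sub("^E:", "", nodes)
  se_ids <- as.character(enhancers$element[enhancers$super])
  type[is.na(type)] <- ifelse(eid[is.na(type)] %in% se_ids, "SE", "TE")
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes,
                                                           type = type))
  g
}

anchor_node <- function(chrom, start, end, is_prom, enhancers, promoters) {
  out <- rep(NA_character_, length(chrom))
  pg_gene <- anchor_gene(chrom, start, end, promoters)
  out[is_prom & !is.na(pg_gene)] <- paste0("P:", pg_gene[is_prom & !is.na(pg_gene)])
  need <- is.na(out)
  if (any(need) && nrow(enhancers) > 0) {
    a <- GenomicRanges::GRanges(chrom[need],
                                IRanges::IRanges(start[need] + 1L, end[need]))
    eg <- df_granges(enhancers)
    ov <- GenomicRanges::findOverlaps(a, eg)
    if (length(ov)) {
      qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
      idx <- which(need)
      w <- pmin(end[idx][qh], enhancers$end[sh]) -
        pmax(start[idx][qh], enhancers$start[sh])
      pick <- vapply(split(seq_along(qh), qh),
                     function(ii) ii[which.max(w[ii])], 0L)
      out[idx[qh[pick]]] <- paste0("E:", enhancers$element[sh[pick]])
    }
  }
  out
}

#' Detect super-enhancer interaction hubs
#'
#' On the subgraph restricted to SE and promoter nodes and to SE-SE / SE-P
#' edges, a connected component is a hub when it contains at least two SEs,
#' at least one promoter, at least one SE-SE edge and at least one SE-P
#' edge — spatially clustered SEs jointly wired to promoters.
#'
#' @param graph graph from [build_ep_network()].
#' @return list of hubs; each has `members` (vertex names), `n_se`,
#'   `n_promoter`, and the subgraph.
#' @export
find_se_hubs <- function(graph) {
  vt <- igraph::V(graph)$type
  keep <- vt %in% c("SE", "promoter")
  sub <- igraph::induced_subgraph(graph, which(keep))
  edge_types <- function(g) {
    e <- igraph::ends(g, igraph::E(g))
    if (nrow(e) == 0) return(character(0))
    t1 <- igraph::V(g)$type[match(e[, 1], igraph::V(g)$name)]
    t2 <- igraph::V(g)$type[match(e[, 2], igraph::V(g)$name)]
    ifelse(t1 == "SE" & t2 == "SE", "SE-SE",
           ifelse((t1 == "SE" & t2 == "promoter") |
                    (t1 == "promoter" & t2 == "SE"), "SE-P", "other"))
  }
  et <- edge_types(sub)
  if (igraph::ecount(sub) > 0)
    sub <- igraph::delete_edges(sub, which(!et %in% c("SE-SE", "SE-P")))
  comp <- igraph::components(sub)
  hubs <- list()
  for (k in seq_len(comp$no)) {
    vids <- which(comp$membership == k)
    cg <- igraph::induced_subgraph(sub, vids)
    types <- igraph::V(cg)$type
    if (sum(types == "SE") < 2 || sum(types == "promoter") < 1) next
    ce <- edge_types(cg)
    if (!any(ce == "SE-SE") || !any(ce == "SE-P")) next
    hubs[[length(hubs) + 1L]] <- list(members = igraph::V(cg)$name,
                                      n_se = sum(types == "SE"),
                                      n_promoter = sum(types == "promoter"),
                                      graph = cg)
  }
  hubs
}

#' Indirect SE-to-promoter associations within a hub
#'
#' SEs of a hub with no direct SE-P edge, but connected to promoters
#' through one or more intermediate SEs, are indirect regulators. Paths run
#' through SE nodes only (promoters are path endpoints).
#'
#' @param hub one element of [find_se_hubs()]'s result.
#' @return `data.frame`: `se`, `promoter`, `path_length` (edges; >= 2).
#' @export
indirect_se_targets <- function(hub) {
  g <- hub$graph
  types <- igraph::V(g)$type
  names <- igraph::V(g)$name
  proms <- names[types == "promoter"]
  ses <- names[types == "SE"]
  direct <- vapply(ses, function(s)
    any(igraph::V(g)$type[igraph::neighbors(g, s)] == "promoter"), TRUE)
  se_sub <- igraph::induced_subgraph(g, which(types == "SE"))
  dmat <- igraph::distances(se_sub)
  out <- list()
  for (s in ses[!direct]) {
    for (p in proms) {
      partners <- igraph::V(g)$name[igraph::neighbors(g, p)]
      partners <- intersect(partners, ses)
      if (length(partners) == 0) next
      dd <- dmat[s, partners]
      dd <- dd[is.finite(dd)]
      if (length(dd) == 0) next
      out[[length(out) + 1L]] <- data.frame(se = s, promoter = p,
                                            path_length = min(dd) + 1)
    }
  }
  if (length(out) == 0)
    return(data.frame(se = character(), promoter = character(),
                      path_length = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Interaction frequency of elements
#'
#' Number of distinct loops with at least one anchor overlapping each
#' element; returned per element with its class, for SE-vs-TE (or
#' super-vs-typical silencer) comparisons.
#'
#' @param elements element `data.frame` with a `class` column.
#' @param loops loop `data.frame`.
#' @return the elements with an `n_loops` column.
#' @export
interaction_frequency <- function(elements, loops) {
  elements$n_loops <- loops_touching(elements, loops)
  elements
}
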