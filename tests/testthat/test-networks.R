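# build a toy annotated-loop frame wiring elements by index: each element a
# 1-kb interval; loops between element midpoints' bins
toy_graph_inputs <- function(edges, se_ids, prom_ids, n_elem = 20) {
  bins <- make_bins(c(chr1 = n_elem * 1e5), 1e4)
  pos <- function(k) (k - 1) * 1e5 + 5e3          # element k center
  elem_ids <- setdiff(seq_len(n_elem), prom_ids)
  enh <- data.frame(chrom = "chr1", start = vapply(elem_ids, pos, 0) - 500,
                    end = vapply(elem_ids, pos, 0) + 500,
                    element = elem_ids, super = elem_ids %in% se_ids,
                    class = ifelse(elem_ids %in% se_ids, "SE", "TE"))
  pr <- data.frame(chrom = "chr1", start = vapply(prom_ids, pos, 0) - 500,
                   end = vapply(prom_ids, pos, 0) + 500,
                   gene_id = paste0("g", prom_ids),
                   tss = vapply(prom_ids, pos, 0), tpm = 10)
  b_of <- function(k) bin_index(bins, "chr1", pos(k))
  loops <- mk_loops(bins, vapply(edges[, 1], b_of, 0L),
                    vapply(edges[, 2], b_of, 0L))
  ann <- annotate_anchors(loops, enh, pr, list(), NULL, NULL)
  list(ann = ann, enh = enh, pr = pr)
}

test_that("one enhancer looped to two promoters forms a 3-node star", {
  fx <- toy_graph_inputs(cbind(c(1, 1), c(2, 3)), se_ids = integer(0),
                         prom_ids = c(2, 3))
  g <- build_ep_network(fx$ann, fx$enh, fx$pr)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)
  expect_equal(igraph::degree(g)[["E:1"]], 2)
})

test_that("duplicate loops collapse into one edge with multiplicity", {
  fx <- toy_graph_inputs(cbind(c(1, 1), c(2, 2)), se_ids = integer(0),
                         prom_ids = 2)
  g <- build_ep_network(fx$ann, fx$enh, fx$pr)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$multiplicity, 2)
})

test_that("planted E-P graph matches a brute-force construction", {
  sim <- cached_sim(1)
  pr <- define_promoters(sim$genes)
  enh <- define_enhancers(rank_and_cut(stitch(sim$peaks$H3K27ac),
                                       mark = "H3K27ac"), pr)
  pl <- sim$truth$loops
  keep <- pl$class %in% c("se_se", "se_p", "ep", "ee", "pp")
  loops <- mk_loops(sim$matrix$bins, pl$bin1[keep], pl$bin2[keep])
  ann <- annotate_anchors(loops, enh, pr, list(), NULL, NULL)
  g <- build_ep_network(ann, enh, pr)
  # brute force: each planted E/P loop is one edge; nodes are its endpoints
  expect_equal(igraph::ecount(g), sum(keep))
  expect_equal(igraph::vcount(g),
               length(unique(c(paste(loops$bin1), paste(loops$bin2)))))
})

test_that("the hub definition follows the SE/promoter micro-examples", {
  # triangle of SEs + promoter looped to one SE -> one hub
  fx <- toy_graph_inputs(rbind(c(1, 2), c(2, 3), c(1, 3), c(3, 4)),
                         se_ids = 1:3, prom_ids = 4)
  hubs <- find_se_hubs(build_ep_network(fx$ann, fx$enh, fx$pr))
  expect_equal(length(hubs), 1)
  expect_setequal(hubs[[1]]$members, c("E:1", "E:2", "E:3", "P:g4"))
  expect_equal(hubs[[1]]$n_se, 3)

  # one SE and one promoter: no SE-SE edge, fewer than 2 SEs -> not a hub
  fx2 <- toy_graph_inputs(cbind(1, 2), se_ids = 1, prom_ids = 2)
  expect_equal(length(find_se_hubs(build_ep_network(fx2$ann, fx2$enh,
                                                    fx2$pr))), 0)

  # two disjoint hub-satisfying components -> two hubs
  fx3 <- toy_graph_inputs(rbind(c(1, 2), c(2, 3), c(5, 6), c(6, 7)),
                          se_ids = c(1, 2, 5, 6), prom_ids = c(3, 7))
  expect_equal(length(find_se_hubs(build_ep_network(fx3$ann, fx3$enh,
                                                    fx3$pr))), 2)

  # TEs cannot bridge two hubs into one component
  fx4 <- toy_graph_inputs(rbind(c(1, 2), c(2, 3), c(2, 10), c(10, 5),
                                c(5, 6), c(6, 7)),
                          se_ids = c(1, 2, 5, 6), prom_ids = c(3, 7))
  expect_equal(length(find_se_hubs(build_ep_network(fx4$ann, fx4$enh,
                                                    fx4$pr))), 2)
})

test_that("indirect SE targets are found through intermediate SEs only", {
  # chain SE1 - SE2 - P: SE1 is an indirect regulator at path length 2
  fx <- toy_graph_inputs(rbind(c(1, 2), c(2, 3)), se_ids = 1:2, prom_ids = 3)
  hubs <- find_se_hubs(build_ep_network(fx$ann, fx$enh, fx$pr))
  ind <- indirect_se_targets(hubs[[1]])
  expect_equal(nrow(ind), 1)
  expect_equal(ind$se, "E:1")
  expect_equal(ind$promoter, "P:g3")
  expect_equal(ind$path_length, 2)

  # an SE with a direct promoter edge is excluded
  fx2 <- toy_graph_inputs(rbind(c(1, 2), c(2, 3), c(1, 3)), se_ids = 1:2,
                          prom_ids = 3)
  hubs2 <- find_se_hubs(build_ep_network(fx2$ann, fx2$enh, fx2$pr))
  expect_equal(nrow(indirect_se_targets(hubs2[[1]])), 0)
})

test_that("direct, indirect and unrelated SE-P pairs partition each hub", {
  fx <- toy_graph_inputs(rbind(c(1, 2), c(2, 3), c(1, 3), c(3, 4), c(6, 7),
                               c(7, 8)),
                         se_ids = c(1, 2, 3, 6, 7), prom_ids = c(4, 8))
  g <- build_ep_network(fx$ann, fx$enh, fx$pr)
  hubs <- find_se_hubs(g)
  all_se <- paste0("E:", c(1, 2, 3, 6, 7))
  all_p <- paste0("P:g", c(4, 8))
  for (se in all_se) for (p in all_p) {
    in_hub <- vapply(hubs, function(h) se %in% h$members && p %in% h$members,
                     TRUE)
    direct <- igraph::are_adjacent(g, se, p)
    indirect <- any(vapply(hubs[in_hub], function(h) {
      it <- indirect_se_targets(h)
      any(it$se == se & it$promoter == p)
    }, TRUE))
    expect_false(direct && indirect)       # never both
    if (!any(in_hub)) expect_false(indirect)  # unrelated pairs stay unrelated
    if (any(in_hub) && !direct) {
      # inside a hub every non-direct SE reaches the promoter indirectly
      # unless it has its own direct promoter edge elsewhere
      se_direct_any <- any(vapply(all_p, function(q)
        igraph::are_adjacent(g, se, q), TRUE))
      if (!se_direct_any) expect_true(indirect)
    }
  }
})

test_that("hub detection is invariant under loop order permutations", {
  fx <- toy_graph_inputs(rbind(c(1, 2), c(2, 3), c(1, 3), c(3, 4), c(5, 6),
                               c(6, 7), c(9, 10)),
                         se_ids = c(1, 2, 3, 5, 6), prom_ids = c(4, 7, 10))
  ref <- find_se_hubs(build_ep_network(fx$ann, fx$enh, fx$pr))
  ref_sets <- lapply(ref, function(h) sort(h$members))
  withr::local_seed(20)
  for (k in 1:100) {
    perm <- sample.int(nrow(fx$ann))
    g <- build_ep_network(fx$ann[perm, ], fx$enh, fx$pr)
    hubs <- find_se_hubs(g)
    sets <- lapply(hubs, function(h) sort(h$members))
    expect_setequal(sets, ref_sets)
  }
})

test_that("SEs interact more frequently than TEs in the planted genome", {
  sim <- cached_sim(1)
  pr <- define_promoters(sim$genes)
  enh <- define_enhancers(rank_and_cut(stitch(sim$peaks$H3K27ac),
                                       mark = "H3K27ac"), pr)
  pl <- sim$truth$loops
  loops <- mk_loops(sim$matrix$bins, pl$bin1, pl$bin2)
  freq <- interaction_frequency(enh, loops)
  expect_gt(median(freq$n_loops[freq$super]),
            median(freq$n_loops[!freq$super]))
  # arithmetic: an element overlapped by 4 distinct loop anchors counts 4
  bins <- make_bins(c(chr1 = 1e6), 1e4)
  el <- data.frame(chrom = "chr1", start = 0, end = 5e4, class = "SE")
  lp <- mk_loops(bins, c(1L, 2L, 3L, 4L), c(20L, 30L, 40L, 50L))
  expect_equal(interaction_frequency(el, lp)$n_loops, 4)
  expect_equal(interaction_frequency(el, lp[0, ])$n_loops, 0)
})
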