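# Topology fixtures built with make_test_graph(); node ids are integers,
# edges are (from, to) pairs.

path_graph <- function(n_edges, support = NULL)
  make_test_graph(seq_len(n_edges), seq_len(n_edges) + 1L, support)

test_that("remove_tips clips short dead ends but not long branches", {
  # trunk 1..11 (10 edges), branch node 11 -> dead end of 2 edges and a
  # continuation of 10 edges
  trunk <- cbind(1:10, 2:11)
  tip <- cbind(c(11, 12), c(12, 13))
  cont <- cbind(c(11, 14:22), c(14:22, 23))
  edges <- rbind(trunk, tip, cont)
  g <- make_test_graph(edges[, 1], edges[, 2])

  g4 <- remove_tips(g, max_tip_len = 4)
  expect_equal(sum(g4$edge_alive), nrow(edges) - 2)   # tip gone
  expect_false(any(g4$edge_alive[11:12]))
  rmapasm:::audit_graph(g4)
  # idempotent
  expect_equal(sum(remove_tips(g4, 4)$edge_alive), sum(g4$edge_alive))

  # threshold boundary: a 2-edge tip survives max_tip_len = 1
  g1 <- remove_tips(g, max_tip_len = 1)
  expect_equal(sum(g1$edge_alive), nrow(edges))
})

test_that("remove_tips leaves unary paths and all-short forks alone", {
  g <- path_graph(6)
  expect_equal(sum(remove_tips(g, 4)$edge_alive), 6)

  # both branches are short dead ends: nothing is removed
  edges <- rbind(cbind(1:3, 2:4), c(4, 5), c(4, 6))
  g <- make_test_graph(edges[, 1], edges[, 2])
  expect_equal(sum(remove_tips(g, 4)$edge_alive), 5)
})

test_that("pop_bubbles disconnects the weaker path at the branching node", {
  # diamond: 1 -> {2,3,4} -> 5 and 1 -> {6,7,8} -> 5, then a tail 5 -> 9
  strong <- cbind(c(1, 2, 3, 4), c(2, 3, 4, 5))
  weak <- cbind(c(1, 6, 7, 8), c(6, 7, 8, 5))
  tail_ <- c(5, 9)
  edges <- rbind(strong, weak, tail_)
  support <- c(5, 5, 5, 5, 2, 2, 2, 2, 3)
  g <- make_test_graph(edges[, 1], edges[, 2], support)

  popped <- pop_bubbles(g, max_bubble_len = 6)
  rmapasm:::audit_graph(popped)
  # only the weak path's FIRST edge is deleted; its remainder survives
  expect_false(popped$edge_alive[5])
  expect_true(all(popped$edge_alive[c(1:4, 6:9)]))
  # idempotent
  expect_equal(pop_bubbles(popped, 6)$edge_alive, popped$edge_alive)

  # paths longer than the threshold are not a bubble
  kept <- pop_bubbles(g, max_bubble_len = 3)
  expect_true(all(kept$edge_alive))
})

test_that("graphs without reconverging paths are unchanged", {
  edges <- rbind(cbind(1:3, 2:4), c(4, 5), c(4, 6), c(5, 7), c(6, 8))
  g <- make_test_graph(edges[, 1], edges[, 2])
  expect_true(all(pop_bubbles(g, 6)$edge_alive))
})

test_that("extract_unitigs reports maximal unary stretches exactly once", {
  g <- path_graph(3)
  paths <- extract_unitigs(g)
  expect_length(paths, 1)
  expect_equal(paths[[1]]$edges, 1:3)
  expect_equal(paths[[1]]$nodes, 1:4)

  # path into a branch: unitig stops at the branching node, branches
  # continue as separate unitigs
  edges <- rbind(cbind(1:3, 2:4), c(4, 5), c(4, 6), c(5, 7))
  g <- make_test_graph(edges[, 1], edges[, 2])
  paths <- extract_unitigs(g)
  lens <- sort(vapply(paths, function(p) length(p$edges), 1L))
  expect_equal(lens, c(1L, 2L, 3L))
  all_edges <- unlist(lapply(paths, `[[`, "edges"))
  expect_equal(sort(all_edges), 1:6)          # every edge exactly once
  # no interior node of any unitig branches
  for (pth in paths)
    for (v in utils::head(pth$nodes[-1], -1)) {
      expect_equal(rmapasm:::in_degree(g, v), 1L)
      expect_equal(rmapasm:::out_degree(g, v), 1L)
    }
})

test_that("cycles terminate the traversal", {
  # entry edge into a 3-cycle: the entry stops at the convergence node,
  # the cycle itself is traversed for exactly one lap
  edges <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 2))
  g <- make_test_graph(edges[, 1], edges[, 2])
  paths <- extract_unitigs(g)
  expect_length(paths, 2)
  expect_equal(sort(unlist(lapply(paths, `[[`, "edges"))), 1:4)
  expect_equal(attr(paths, "n_cyclic_edges"), 0L)

  # purely cyclic component: unreachable, counted
  edges <- rbind(c(1, 2), c(2, 1))
  g <- make_test_graph(edges[, 1], edges[, 2])
  paths <- extract_unitigs(g)
  expect_length(paths, 0)
  expect_equal(attr(paths, "n_cyclic_edges"), 2L)
})

test_that("a single-edge path spells the bi-label itself", {
  p <- toy_params()
  b <- bl_from_list(list(bilabel(c(7, 18, 13), c(3, 15, 12), c(4, 3, 6),
                                 "r", 1L)))
  g <- glue_nodes(build_graph(b, p), p)
  ct <- spell_contig(extract_unitigs(g)[[1]], g, p)
  expect_equal(ct$fragments, c(7, 18, 13, 3, 15, 12, 4, 3, 6))
  expect_equal(ct$n_frags, 9)
  expect_equal(ct$genomic_length, sum(ct$fragments))
})

test_that("consecutive bi-labels spell the underlying Rmap segment", {
  p <- toy_params()
  bls <- extract_bilabels(rmap("R", fig_fragments), p)
  two <- bl_subset(bls, 1:2)
  g <- glue_nodes(build_graph(two, p), p)
  ct <- spell_contig(extract_unitigs(g)[[1]], g, p)
  # position 1 through the end of the second bi-label (fragment 9)
  expect_equal(ct$fragments, fig_fragments[1:9])
  expect_equal(ct$n_frags, (2 - 1) + 3 + 2 + 3)

  # all three bi-labels spell the full Rmap
  g <- glue_nodes(build_graph(bls, p), p)
  ct <- spell_contig(extract_unitigs(g)[[1]], g, p)
  expect_equal(ct$fragments, fig_fragments)
})

test_that("consensus fragments are member means rounded to bp", {
  p <- toy_params(t_f = 3, t_l = 9)
  mk <- function(d, id) bilabel(c(10, 20, 30) + d, c(40, 50) + d,
                                c(60, 70, 80) + d, "r", id)
  s <- compute_support(bl_from_list(list(mk(0, 1L), mk(1, 2L), mk(2, 3L))),
                       p)
  red <- reduce_to_representatives(s, p)
  expect_equal(red$representatives$n, 1)
  g <- glue_nodes(build_graph(red, p), p)
  ct <- spell_contig(extract_unitigs(g)[[1]], g, p)
  expect_equal(ct$fragments, c(11, 21, 31, 41, 51, 61, 71, 81))
  expect_equal(ct$support_profile, 3L)
})

test_that("non-proximal junctions raise an assembly-integrity error", {
  g <- make_test_graph(c(1, 2), c(2, 3))
  g$edge_bilabel[[2]] <- bilabel(c(100, 100, 100), 500, c(100, 100, 100))
  fake_path <- list(nodes = 1:3, edges = 1:2)
  expect_error(spell_contig(fake_path, g, toy_params(D = 5)),
               "assembly-integrity")
  # and edges that do not even share a node
  g2 <- make_test_graph(c(1, 3), c(2, 4))
  expect_error(spell_contig(list(nodes = c(1, 2, 4), edges = 1:2), g2,
                            toy_params(D = 5)),
               "assembly-integrity")
})
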