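test_that("support counting matches brute-force pair counting", {
  p <- toy_params(t_f = 2, t_l = 5)

  single <- bl_from_list(list(bilabel(c(1, 2, 3), 30, c(4, 5, 6), "r", 1L)))
  expect_equal(compute_support(single, p)$support, 0L)

  dup <- bl_from_list(lapply(1:5, function(i)
    bilabel(c(10, 20, 30), 40, c(5, 6, 7), "r", i)))
  expect_equal(compute_support(dup, p)$support, rep(4L, 5))

  set.seed(31)
  s <- random_bilabel_set(300)
  s <- compute_support(s, p)
  want <- vapply(seq_len(s$n), function(i)
    length(oracle_proximal_of(s, i, p$t_f, p$t_l)), 1L)
  expect_equal(s$support, want)
})

test_that("low-frequency filtering keeps exactly support >= min_support", {
  p <- toy_params(t_f = 1, t_l = 1)
  mk <- function(base, n, id0) lapply(seq_len(n), function(i)
    bilabel(base, sum(base), base, "r", id0 + i))
  # groups of exact duplicates of sizes 1, 3, 5
  s <- bl_from_list(c(mk(c(1, 2, 3), 1, 0), mk(c(50, 60, 70), 3, 10),
                      mk(c(200, 300, 400), 5, 20)))
  s <- compute_support(s, p)
  expect_equal(bl_subset(s, which(s$support >= 0))$n,
               filter_low_frequency(s, 0)$n)  # min_support 0 is identity
  expect_equal(filter_low_frequency(s, 1)$n, 8)   # singleton dropped
  expect_equal(filter_low_frequency(s, 3)$n, 5)   # only the group of 5
  expect_error(filter_low_frequency(bl_from_list(mk(c(1, 2, 3), 2, 0)), 1),
               "supports not computed")
})

test_that("reduction keeps pairwise non-proximal inputs unchanged", {
  p <- toy_params(t_f = 1, t_l = 2)
  s <- bl_from_list(lapply(c(10, 100, 1000), function(x)
    bilabel(c(x, x, x), x * 3, c(x, x, x), "r", x)))
  s <- compute_support(s, p)
  red <- reduce_to_representatives(s, p)
  expect_equal(red$representatives$n, 3)
  expect_equal(red$edge_support, rep(1L, 3))
})

test_that("reduction groups proximal bi-labels under representatives", {
  # two proximal pairs and one singleton: 3 representatives
  p <- toy_params(t_f = 2, t_l = 4)
  b1 <- bilabel(c(7, 18, 13), c(3, 15, 12), c(4, 3, 6), "R1", 1L)
  b2 <- bilabel(c(18, 13, 3), c(15, 12), c(4, 3, 6), "R1", 2L)
  b3 <- bilabel(c(13, 3, 15), c(12, 4, 3, 6), c(5, 13, 2), "R1", 3L)
  b4 <- bilabel(c(8, 17, 13), c(3, 16, 12), c(4, 4, 6), "R2", 1L)   # ~ b1
  b5 <- bilabel(c(17, 13, 4), c(16, 12), c(4, 4, 6), "R2", 2L)      # ~ b2
  s <- compute_support(bl_from_list(list(b1, b2, b3, b4, b5)), p)
  expect_equal(s$support, c(1L, 1L, 0L, 1L, 1L))
  red <- reduce_to_representatives(s, p)
  expect_equal(red$representatives$n, 3)
  expect_equal(sum(red$edge_support), 5)  # conservation
  # every input is proximal to (or is) its representative
  for (i in seq_len(s$n)) {
    r <- red$rep_of[i]
    expect_true(is_proximal(bl_get(s, i),
                            bl_get(red$representatives, r),
                            p$t_f, p$t_l))
  }
})

test_that("reduction satisfies the coverage property on random inputs", {
  set.seed(32)
  p <- toy_params(t_f = 2, t_l = 5)
  for (rep in 1:3) {
    s <- compute_support(random_bilabel_set(250), p)
    red <- reduce_to_representatives(s, p)
    expect_equal(sum(red$edge_support), s$n)
    reps <- red$representatives
    covered <- vapply(seq_len(s$n), function(i) {
      bi <- bl_get(s, i)
      any(vapply(seq_len(reps$n), function(r)
        is_proximal(bi, bl_get(reps, r), p$t_f, p$t_l), TRUE))
    }, TRUE)
    expect_true(all(covered))
    # representatives are pairwise non-proximal
    clash <- FALSE
    for (i in seq_len(reps$n - 1))
      for (j in (i + 1):reps$n)
        clash <- clash || is_proximal(bl_get(reps, i), bl_get(reps, j),
                                      p$t_f, p$t_l)
    expect_false(clash)
  }
})

test_that("build_graph creates one edge per representative with exact node dedup", {
  p <- toy_params()
  single <- bl_from_list(list(bilabel(c(7, 18, 13), c(3, 15, 12),
                                      c(4, 3, 6), "r", 1L)))
  g <- build_graph(single, p)
  expect_equal(sum(g$edge_alive), 1)
  expect_equal(sum(g$node_alive), 2)
  rmapasm:::audit_graph(g)

  # three chained-but-perturbed bi-labels: 6 distinct node slots before
  # gluing, then a 4-node path after
  b1 <- bilabel(c(7, 18, 13), c(3, 15, 12), c(4, 3, 6), "R1", 1L)
  b5 <- bilabel(c(17, 13, 4), c(16, 12), c(4, 4, 6), "R2", 2L)
  b3 <- bilabel(c(13, 3, 15), c(12, 4, 3, 6), c(5, 13, 2), "R1", 3L)
  p2 <- toy_params(t_f = 2, t_l = 4)
  g <- build_graph(bl_from_list(list(b1, b5, b3)), p2)
  expect_equal(sum(g$node_alive), 6)
  g <- glue_nodes(g, p2)
  rmapasm:::audit_graph(g)
  expect_equal(sum(g$node_alive), 4)
  expect_equal(sum(g$edge_alive), 3)
  degs <- t(vapply(rmapasm:::live_nodes(g), function(v)
    c(rmapasm:::in_degree(g, v), rmapasm:::out_degree(g, v)), c(1L, 1L)))
  expect_equal(sort(colSums(degs)), c(3L, 3L))          # 3 edges each way
  expect_equal(sum(degs[, 1] == 0), 1)                  # one source
  expect_equal(sum(degs[, 2] == 0), 1)                  # one sink
})

test_that("an error-free chain glues into a simple path", {
  p <- toy_params()
  set.seed(33)
  f <- sample(5:30, 30, replace = TRUE)
  bls <- extract_bilabels(rmap("r", f), p)
  g <- glue_nodes(build_graph(bls, p), p)
  rmapasm:::audit_graph(g)
  expect_equal(sum(g$edge_alive), length(bls))
  expect_equal(sum(g$node_alive), length(bls) + 1)
  paths <- extract_unitigs(g)
  expect_length(paths, 1)
  expect_length(paths[[1]]$edges, length(bls))
})

test_that("gluing leaves no live proximal node pair", {
  set.seed(34)
  p <- toy_params(t_f = 2, t_l = 5)
  for (rep in 1:3) {
    s <- compute_support(random_bilabel_set(150), p)
    red <- reduce_to_representatives(filter_low_frequency(s, 1), p)
    g <- glue_nodes(build_graph(red, p), p)
    rmapasm:::audit_graph(g)
    live <- rmapasm:::live_nodes(g)
    clash <- FALSE
    for (i in seq_along(live))
      for (j in seq_len(i - 1))
        clash <- clash || is_proximal(g$nodes[[live[i]]],
                                      g$nodes[[live[j]]], p$t_f, p$t_l)
    expect_false(clash)
  }
})
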