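test_that("extraction reproduces the printed bi-labels of the 12-fragment Rmap", {
  p <- toy_params()
  bls <- extract_bilabels(rmap("R", fig_fragments), p)
  expect_equal(length(bls), 3)
  b <- lapply(1:3, function(i) bl_get(bls, i))
  expect_equal(b[[1]]$kmer1, c(7, 18, 13))
  expect_equal(b[[1]]$skip, c(3, 15, 12))
  expect_equal(b[[1]]$kmer2, c(4, 3, 6))
  expect_equal(b[[2]]$kmer1, c(18, 13, 3))
  expect_equal(b[[2]]$skip, c(15, 12))
  expect_equal(b[[2]]$kmer2, c(4, 3, 6))
  expect_equal(b[[3]]$kmer1, c(13, 3, 15))
  expect_equal(b[[3]]$skip, c(12, 4, 3, 6))
  expect_equal(b[[3]]$kmer2, c(5, 13, 2))
  expect_equal(vapply(b, `[[`, 1L, "pos"), 1:3)
})

test_that("Rmaps too short for two k-mers plus a skip yield nothing", {
  p <- toy_params()
  expect_equal(length(extract_bilabels(rmap("s", rep(10, 6)), p)), 0)
  expect_equal(length(extract_bilabels(rmap("s", 5), p)), 0)
})

test_that("extraction agrees with the exhaustive (i, q) oracle", {
  set.seed(11)
  for (rep in 1:30) {
    f <- sample(1:30, 40, replace = TRUE)
    k <- sample(2:4, 1)
    D <- sample(20:60, 1)
    got <- extract_bilabels(rmap("r", f), rmap_params(k = k, D = D,
                                                      t_f = 1, t_l = 1))
    got_list <- lapply(seq_len(length(got)), function(i) {
      b <- bl_get(got, i)
      list(kmer1 = b$kmer1, skip = b$skip, kmer2 = b$kmer2, pos = b$pos)
    })
    expect_equal(got_list, oracle_bilabels(f, k, D))
  }
})

test_that("extracted skip segments are minimal", {
  set.seed(12)
  for (rep in 1:10) {
    f <- sample(1:30, 40, replace = TRUE)
    p <- rmap_params(k = 3, D = 40, t_f = 1, t_l = 1)
    bls <- extract_bilabels(rmap("r", f), p)
    ok <- vapply(bls$skips, function(s)
      sum(s) >= p$D && sum(s) - s[length(s)] < p$D, TRUE)
    expect_true(all(ok))
  }
})

test_that("both_directions adds reverse-extracted bi-labels", {
  p <- toy_params(both_directions = TRUE)
  bls <- extract_bilabels(rmap("R", fig_fragments), p)
  fwd <- bls$orientation == "forward"
  expect_equal(sum(fwd), 3)
  # reverse bi-labels equal extraction from the reversed fragment list
  p1 <- toy_params()
  revs <- extract_bilabels(rmap("R", rev(fig_fragments)), p1)
  expect_equal(bls$kmers[!fwd, , drop = FALSE], revs$kmers)
  expect_true(all(bls$orientation[!fwd] == "reverse"))
})

test_that("prefix/suffix bi-labels match the hand-derived examples", {
  p <- toy_params()
  b2 <- bilabel(c(18, 13, 3), c(15, 12), c(4, 3, 6))
  pre <- prefix_bilabel(b2, p)
  expect_equal(pre$kmer1, c(18, 13))
  expect_equal(pre$skip, c(3, 15, 12))  # 3+15 = 18 < 25 <= 30
  expect_equal(pre$kmer2, c(4, 3))

  b1 <- bilabel(c(7, 18, 13), c(3, 15, 12), c(4, 3, 6))
  suf <- suffix_bilabel(b1, p)
  expect_equal(suf$kmer1, c(18, 13))
  expect_equal(suf$skip, c(3, 15, 12))
  expect_equal(suf$kmer2, c(4, 3))

  # single-fragment skip >= D forces a single-fragment prefix skip
  b <- bilabel(c(5, 5, 30), c(26), c(7, 8, 9))
  pre <- prefix_bilabel(b, p)
  expect_equal(pre$kmer1, c(5, 5))
  expect_equal(pre$skip, 30)
  expect_equal(pre$kmer2, c(26, 7))

  # k = 2: first (k-1)-mer of the suffix is the last fragment of kmer1
  bk2 <- bilabel(c(9, 30), c(26), c(7, 8))
  expect_equal(suffix_bilabel(bk2, p)$kmer1, 30)
  bk1 <- bilabel(5, 26, 7)
  expect_error(prefix_bilabel(bk1, p), "k = 1")
  expect_error(suffix_bilabel(bk1, p), "k = 1")
})

test_that("chain property: suffix(b_i) equals prefix(b_{i+1})", {
  chain_holds <- function(f, p) {
    bls <- extract_bilabels(rmap("r", f), p)
    n <- length(bls)
    if (n < 2) return(TRUE)
    all(vapply(seq_len(n - 1), function(i) {
      a <- suffix_bilabel(bl_get(bls, i), p)
      b <- prefix_bilabel(bl_get(bls, i + 1), p)
      identical(a$kmer1, b$kmer1) && identical(a$skip, b$skip) &&
        identical(a$kmer2, b$kmer2)
    }, TRUE))
  }
  expect_true(chain_holds(fig_fragments, toy_params()))
  set.seed(13)
  ok <- vapply(1:40, function(rep)
    chain_holds(sample(1:30, 40, replace = TRUE),
                rmap_params(k = sample(2:4, 1), D = sample(20:50, 1),
                            t_f = 1, t_l = 1)), TRUE)
  expect_true(all(ok))
})

test_that("prefix/suffix agree with recomputation from the source Rmap", {
  set.seed(14)
  p <- rmap_params(k = 4, D = 35, t_f = 1, t_l = 1)
  for (rep in 1:10) {
    f <- sample(1:30, 40, replace = TRUE)
    bls <- extract_bilabels(rmap("r", f), p)
    pk <- rmap_params(k = 3, D = 35, t_f = 1, t_l = 1)
    small <- extract_bilabels(rmap("r", f), pk)
    ok <- vapply(seq_len(length(bls)), function(i) {
      b <- bl_get(bls, i)
      pre <- prefix_bilabel(b, p)
      # the (k-1) bi-label at the same position in the full Rmap
      j <- which(small$pos == b$pos)
      identical(pre$kmer1, as.numeric(small$kmers[j, 1:3])) &&
        identical(pre$skip, small$skips[[j]]) &&
        identical(pre$kmer2, as.numeric(small$kmers[j, 4:6]))
    }, TRUE)
    expect_true(all(ok))
  }
})

test_that("proximity predicates match their definitions", {
  a <- bilabel(c(5, 6, 7, 11, 5), c(30), c(5, 6, 7, 11, 5))
  b <- bilabel(c(6, 5, 6, 11, 6), c(30), c(6, 5, 6, 11, 6))
  expect_true(fragment_proximal(a, b, 1))
  expect_false(fragment_proximal(a, b, 0))
  expect_true(is_proximal(a, b, 1, 5))

  # reflexive + symmetric
  expect_true(is_proximal(a, a, 0, 0))
  expect_equal(fragment_proximal(a, b, 1), fragment_proximal(b, a, 1))

  # skip-length boundary
  c1 <- bilabel(c(5, 5), c(30), c(5, 5))
  c2 <- bilabel(c(5, 5), c(30 + 3 + 1), c(5, 5))
  expect_false(length_proximal(c1, c2, 3))
  expect_true(length_proximal(c1, bilabel(c(5, 5), c(33), c(5, 5)), 3))

  expect_error(fragment_proximal(a, c1, 1), "different k")
  expect_error(length_proximal(a, c1, 1), "different k")
})

test_that("proximity matches a direct loop oracle on random pairs", {
  set.seed(15)
  for (rep in 1:50) {
    k <- sample(2:5, 1)
    a <- bilabel(sample(1:40, k), sample(1:40, sample(1:3, 1), TRUE),
                 sample(1:40, k))
    b <- bilabel(pmax(1, a$kmer1 + sample(-4:4, k, TRUE)),
                 sample(1:40, sample(1:3, 1), TRUE),
                 pmax(1, a$kmer2 + sample(-4:4, k, TRUE)))
    t_f <- sample(0:5, 1); t_l <- sample(0:10, 1)
    frag_ok <- TRUE
    for (i in 1:k)
      frag_ok <- frag_ok && abs(a$kmer1[i] - b$kmer1[i]) <= t_f &&
        abs(a$kmer2[i] - b$kmer2[i]) <= t_f
    len_ok <- abs(sum(a$kmer1) - sum(b$kmer1)) <= t_l &&
      abs(sum(a$kmer2) - sum(b$kmer2)) <= t_l &&
      abs(sum(a$skip) - sum(b$skip)) <= t_l
    expect_equal(fragment_proximal(a, b, t_f), frag_ok)
    expect_equal(length_proximal(a, b, t_l), len_ok)
    expect_equal(is_proximal(a, b, t_f, t_l), frag_ok && len_ok)
  }
})

test_that("the skip segment absorbs a missed cut site", {
  # two Rmaps identical except two adjacent skip-interior fragments merged
  p <- toy_params()
  f1 <- fig_fragments
  f2 <- c(f1[1:4], f1[5] + f1[6], f1[7:12])  # merge 15 and 12
  b1 <- bl_get(extract_bilabels(rmap("R", f1), p), 1)
  b1p <- bl_get(extract_bilabels(rmap("Rp", f2), p), 1)
  expect_equal(b1p$skip, c(3, 27))           # fewer fragments, same length
  expect_true(is_proximal(b1, b1p, 0, 0))    # exactly length-preserving
})
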