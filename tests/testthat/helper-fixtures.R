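# Shared fixtures and independent oracles. Oracles deliberately avoid the
# package's own code paths (direct loops over the defining inequalities).

fig_fragments <- c(7, 18, 13, 3, 15, 12, 4, 3, 6, 5, 13, 2)

toy_params <- function(...) {
  defaults <- list(k = 3, D = 25, t_f = 1, t_l = 3, min_support = 0,
                   min_contig_frags = 1)
  do.call(rmap_params, utils::modifyList(defaults, list(...)))
}

# enumerate every (i, q) pair and test the bi-label inequalities directly
oracle_bilabels <- function(f, k, D) {
  n <- length(f)
  out <- list()
  for (i in seq_len(n)) {
    p <- i + k
    if (i + k - 1 > n) next
    for (q in seq_len(n)) {
      if (q < p || q + k > n) next
      lpq <- sum(f[p:q])
      lprev <- if (q - 1 >= p) sum(f[p:(q - 1)]) else 0
      if (lprev < D && D <= lpq)
        out[[length(out) + 1]] <- list(kmer1 = f[i:(i + k - 1)],
                                       skip = f[p:q],
                                       kmer2 = f[(q + 1):(q + k)],
                                       pos = i)
    }
  }
  out
}

# brute-force proximal set of item i within a bilabel_set (vectorised scan,
# no trees, no buckets)
oracle_proximal_of <- function(set, i, t_f, t_l) {
  dk <- abs(sweep(set$kmers, 2, set$kmers[i, ])) <= t_f
  dl <- abs(sweep(set$lens, 2, set$lens[i, ])) <= t_l
  which(rowSums(dk) == ncol(set$kmers) & rowSums(dl) == 3 &
          seq_len(set$n) != i)
}

# bilabel sets with realistic proximal structure: jittered copies of base
# Rmaps, bi-labels extracted from them
random_bilabel_set <- function(n_target, k = 3, D = 25, copies = 4,
                               jitter = 2, frag_lo = 5, frag_hi = 40,
                               rmap_len = 40) {
  p <- rmap_params(k = k, D = D, t_f = 1, t_l = 1, min_support = 0)
  sets <- list()
  b <- 0
  repeat {
    b <- b + 1
    base <- sample(frag_lo:frag_hi, rmap_len, replace = TRUE)
    for (cp in seq_len(copies)) {
      f <- pmax(1, base + sample(-jitter:jitter, rmap_len, replace = TRUE))
      s <- extract_bilabels(rmap(sprintf("r%d_%d", b, cp), f), p)
      if (s$n > 0) sets[[length(sets) + 1]] <- s
    }
    s <- rmapasm:::bl_bind(sets)
    if (s$n >= n_target) return(bl_subset(s, seq_len(n_target)))
  }
}

# construct a bilabel_graph directly from topology (labels are synthetic
# chains; used by the cleanup tests, which only read topology and support)
make_test_graph <- function(edge_from, edge_to, support = NULL,
                            params = toy_params()) {
  nn <- max(edge_from, edge_to)
  if (is.null(support)) support <- rep(1L, length(edge_from))
  nodes <- lapply(seq_len(nn), function(i)
    bilabel(c(10 + i, 20 + i), c(30 + i), c(40 + i, 50 + i)))
  g <- rmapasm:::new_bilabel_graph(
    k = 3L, params = params, nodes = nodes,
    node_keys = vapply(nodes, rmapasm:::node_label_key, ""),
    edge_from = as.integer(edge_from), edge_to = as.integer(edge_to),
    edge_support = as.integer(support),
    edge_bilabel = rep(list(bilabel(c(1, 1, 1), 5, c(1, 1, 1))),
                       length(edge_from)),
    edge_members = rep(list(NULL), length(edge_from)))
  g
}

# write a temporary Rmap text file from fragment lists (in bp)
write_rmap_text <- function(frag_lists, path) {
  rs <- lapply(seq_along(frag_lists), function(i)
    rmap(paste0("m", i), frag_lists[[i]]))
  write_rmaps(rs, path)
}
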