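# Independent brute-force oracles, deliberately naive: they enumerate the
# whole search space and never share code with the package internals.

# leaf interval by enumerating the 2^k leaves and walking each one's
# ancestor chain: leaf j (1-based) has depth-d ancestor index (j-1) %/%
# 2^(k-d); the node's interval is the range of leaves owning it
oracle_leaf_interval <- function(depth, index, k) {
  leaves <- seq_len(2^k)
  anc <- (leaves - 1) %/% 2^(k - depth)
  range(leaves[anc == index])
}

# every feasible (t, node, block) triple for a position set: regenerate and
# compare, nothing cleverer
oracle_enum_fits <- function(G, k) {
  G <- sort(G)
  res <- list()
  Mmax <- ceiling((max(G) + 2^k - 1) / 2^k) + 1
  for (t in 0:(2^k - 1)) for (d in 0:k) for (i in 0:(2^d - 1)) {
    w <- 2^(k - d)
    lo <- i * w + 1
    for (mlo in 1:Mmax) for (mhi in mlo:Mmax) {
      legs <- unlist(lapply(mlo:mhi, function(m)
        (m - 1) * 2^k + lo:(lo + w - 1) - t))
      if (all(legs >= 1) && length(legs) == length(G) &&
          all(sort(legs) == G))
        res[[length(res) + 1]] <-
          c(t = t, depth = d, index = i, mlo = mlo, mhi = mhi)
    }
  }
  if (length(res)) do.call(rbind, res) else NULL
}

# the package's preference order, applied to the oracle's candidate list:
# depth asc, index desc, t asc
oracle_best_fit <- function(G, k) {
  f <- oracle_enum_fits(G, k)
  if (is.null(f)) return(NULL)
  f[order(f[, "depth"], -f[, "index"], f[, "t"]), , drop = FALSE][1, ]
}
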