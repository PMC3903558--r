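test_that("run decomposition recovers the published run structures", {
  d <- decompose_runs(c(8:11, 24:27))
  expect_equal(d$runs, cbind(start = c(8L, 24L), end = c(11L, 27L)))
  expect_equal(d$spacings, 16L)          # posterior set displaced by 16

  d2 <- decompose_runs(c(4, 8, 12))
  expect_equal(nrow(d2$runs), 3)
  expect_equal(d2$spacings, c(4L, 4L))

  d3 <- decompose_runs(5)
  expect_equal(d3$runs, cbind(start = 5L, end = 5L))
  expect_length(d3$spacings, 0)

  expect_equal(nrow(decompose_runs(integer())$runs), 0)
})

test_that("cycle inference accepts only a single power-of-2 spacing", {
  expect_equal(infer_cycles(decompose_runs(c(8:11, 24:27))),
               list(defined = TRUE, k = 4L, reason = ""))
  expect_equal(infer_cycles(decompose_runs(c(4, 8, 12)))$k, 2L)
  expect_equal(infer_cycles(decompose_runs(c(1, 7)))$reason,
               "not a power of 2")
  expect_equal(infer_cycles(decompose_runs(c(1, 5, 13)))$reason,
               "unequal spacings")
  expect_false(infer_cycles(decompose_runs(c(8, 9)))$defined)
})

test_that("dyadic_fit reproduces the oracle on the three published patterns", {
  # homeotic julidan: posterior quarter of primary segments 1-2, anchor 5
  f <- dyadic_fit(c(8:11, 24:27), 4)
  o <- oracle_best_fit(c(8:11, 24:27), 4)
  expect_true(f$feasible)
  expect_equal(unname(coef(f)[c("anchor", "depth", "index",
                                "block_lo", "block_hi")]),
               unname(o[c("t", "depth", "index", "mlo", "mhi")]))
  expect_equal(f$anchor, 5)
  expect_equal(c(f$node$depth, f$node$index), c(2, 3))
  expect_equal(f$block, c(1, 2))
  expect_equal(f$multiplicative_cost, 1)
  expect_equal(f$sequential_cost, 2)
  expect_true(f$informative)

  # polydesmidan: posterior leaf of primary segments 1-3, anchor 0
  f2 <- dyadic_fit(c(4, 8, 12), 2)
  expect_equal(f2$anchor, 0)
  expect_equal(c(f2$node$depth, f2$node$index), c(2, 3))
  expect_equal(f2$block, c(1, 3))
  o2 <- oracle_best_fit(c(4, 8, 12), 2)
  expect_equal(unname(o2[c("t", "depth", "index")]), c(0, 2, 3))

  # normal male under the julidan default anchor: node (3,6), one module
  f3 <- dyadic_fit(c(8, 9), 4, anchor = 5)
  expect_true(f3$feasible)
  expect_equal(c(f3$node$depth, f3$node$index), c(3, 6))
  expect_equal(f3$block, c(1, 1))
  expect_false(f3$informative)   # one block: no spacing evidence
})

test_that("a contiguous extension fits only within a single block", {
  f <- dyadic_fit(c(7, 8), 4)
  expect_true(f$feasible)
  expect_equal(f$block[2] - f$block[1], 0)
  expect_false(f$informative)
  o <- oracle_enum_fits(c(7, 8), 4)
  expect_true(all(o[, "mlo"] == o[, "mhi"]))   # no multi-module fit exists
})

test_that("feasible fits regenerate the observed set exactly (soundness)", {
  set.seed(7)
  for (rep in 1:30) {
    k <- sample(1:5, 1)
    G <- sort(sample(1:40, sample(1:8, 1)))
    f <- dyadic_fit(G, k)
    if (f$feasible) {
      expect_identical(predict(f), as.integer(G))
      expect_equal(residuals(f), list(missed = integer(),
                                      unexplained = integer()))
    }
  }
})

test_that("dyadic_fit agrees with exhaustive enumeration for k <= 3, |G| <= 12", {
  set.seed(13)
  for (rep in 1:60) {
    k <- sample(0:3, 1)
    G <- sort(sample(1:24, sample(1:12, 1)))
    f <- dyadic_fit(G, k)
    o <- oracle_best_fit(G, k)
    if (is.null(o)) {
      expect_false(f$feasible,
                   info = sprintf("k=%d G={%s}", k, paste(G, collapse = ",")))
    } else {
      expect_true(f$feasible,
                  info = sprintf("k=%d G={%s}", k, paste(G, collapse = ",")))
      expect_equal(unname(coef(f)[c("anchor", "depth", "index",
                                    "block_lo", "block_hi")]),
                   unname(o[c("t", "depth", "index", "mlo", "mhi")]),
                   info = sprintf("k=%d G={%s}", k, paste(G, collapse = ",")))
    }
  }
})

test_that("fits are translation-invariant up to a one-module shift", {
  set.seed(29)
  for (rep in 1:20) {
    k <- sample(1:4, 1)
    G <- sort(sample(1:30, sample(2:6, 1)))
    f1 <- dyadic_fit(G, k)
    f2 <- dyadic_fit(G + as.integer(2^k), k)
    expect_equal(f2$feasible, f1$feasible)
    if (f1$feasible) {
      expect_equal(c(f2$node$depth, f2$node$index),
                   c(f1$node$depth, f1$node$index))
      expect_equal(f2$block, f1$block + 1L)
      expect_equal(f2$anchor, f1$anchor)
    }
  }
})

test_that("the minimal event cover prices infeasible patterns", {
  # the Madeira pattern needs two marker events at any anchor
  f <- dyadic_fit(c(8, 9, 11), 4)
  expect_false(f$feasible)
  expect_equal(f$multiplicative_cost, 2)
  expect_equal(f$sequential_cost, 2)
  # cost is skipped on request
  expect_true(is.na(dyadic_fit(c(8, 9, 11), 4,
                               compute_cost = FALSE)$multiplicative_cost))
  # two singletons a module apart merge into one translated-leaf event
  expect_equal(dyadic_fit(c(1, 4, 12), 3)$multiplicative_cost, 2)
  # three scattered singletons with non-dyadic spacings need three events
  expect_equal(dyadic_fit(c(1, 4, 6), 3)$multiplicative_cost, 3)
})

test_that("the event-cover minimum matches naive subset enumeration", {
  oracle_min_cover <- function(G, k) {
    G <- sort(unique(as.integer(G)))
    best <- length(G)
    Mmax <- ceiling((max(G) + 2^k - 1) / 2^k) + 1
    for (t in 0:(2^k - 1)) {
      ev <- list()
      for (d in 0:k) for (i in 0:(2^d - 1)) {
        w <- 2^(k - d); lo <- i * w + 1
        for (mlo in 1:Mmax) for (mhi in mlo:Mmax) {
          pos <- unlist(lapply(mlo:mhi, function(m)
            (m - 1) * 2^k + lo:(lo + w - 1) - t))
          if (all(pos >= 1) && all(pos %in% G))
            ev[[length(ev) + 1]] <- pos
        }
      }
      ev <- unique(ev)
      if (!length(ev)) next
      for (size in 1:(best - 1)) {
        found <- FALSE
        for (cb in utils::combn(length(ev), size, simplify = FALSE)) {
          u <- as.integer(sort(unique(unlist(ev[cb]))))
          if (identical(u, G)) { found <- TRUE; break }
        }
        if (found) { best <- min(best, size); break }
      }
    }
    best
  }
  set.seed(61)
  for (rep in 1:10) {
    k <- sample(1:2, 1)
    G <- sort(sample(1:16, sample(2:5, 1)))
    f <- dyadic_fit(G, k)
    cost <- if (f$feasible) 1L else f$multiplicative_cost
    expect_equal(cost, oracle_min_cover(G, k),
                 info = sprintf("k=%d G={%s}", k, paste(G, collapse = ",")))
  }
})

test_that("a tolerance budget admits near-miss patterns", {
  f <- dyadic_fit(c(8, 9, 10, 11, 24, 25, 26), 4, max_mismatch = 1)
  expect_true(f$feasible)
  expect_equal(f$mismatch, 27L)   # the one position the event adds
  expect_equal(c(f$node$depth, f$node$index), c(2, 3))
})

test_that("model comparison reaches the published verdicts", {
  fx <- fixtures()
  cmp <- compare_models(fx$homeotic_ommatoiulus)
  expect_equal(cmp$verdict, "multiplicative-consistent")
  expect_equal(cmp$consistent_k, 4L)      # at k = 4 only
  expect_equal(cmp$k_hat$k, 4L)
  expect_length(cmp$diff, 0)              # regenerated pattern is exact

  expect_equal(compare_models(fx$madeira_ommatoiulus)$verdict,
               "contiguous-anomaly")
  expect_equal(compare_models(fx$pseudoeurydesmus)$verdict,
               "uninformative-one-run")
  expect_equal(compare_models(fx$normal_ommatoiulus)$verdict,
               "uninformative-one-run")
  expect_equal(compare_models(fx$homeotic_nannaria)$verdict,
               "multiplicative-consistent")
  expect_equal(compare_models(fx$homeotic_nannaria)$consistent_k, 2L)

  empty <- phenotype(data.frame(leg_pair = 1:3,
                                state_left = "WALKING_LEG",
                                state_right = "WALKING_LEG"))
  expect_equal(compare_models(empty)$verdict, "no-gonopods")
})
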