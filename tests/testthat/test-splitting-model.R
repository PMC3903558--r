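test_that("expand_units realizes P*2^k - t contiguous units with consistent coordinates", {
  u <- expand_units(splitting_spec(k = 4, P = 2, t = 5))
  expect_equal(nrow(u), 27)
  expect_identical(u$leg_pair, 1:27)
  expect_equal(unlist(u[u$leg_pair == 8, c("primary_segment", "offset")]),
               c(primary_segment = 1, offset = 13))
  expect_equal(unlist(u[u$leg_pair == 24, c("primary_segment", "offset")]),
               c(primary_segment = 2, offset = 13))
  expect_true(all(u$state_left == "WALKING_LEG" &
                    u$state_right == "WALKING_LEG"))

  # no splitting: one unit per primary segment
  u0 <- expand_units(splitting_spec(k = 0, P = 3, t = 0))
  expect_equal(nrow(u0), 3)
  expect_true(all(u0$offset == 1))

  # polydesmidan-scale grid
  u2 <- expand_units(splitting_spec(k = 2, P = 4, t = 0))
  expect_equal(nrow(u2), 16)
  expect_equal(unlist(u2[u2$leg_pair == 8, c("primary_segment", "offset")]),
               c(primary_segment = 2, offset = 4))
})

test_that("unit count and coordinate formula hold over random specs", {
  set.seed(41)
  for (rep in 1:50) {
    k <- sample(0:5, 1)
    P <- sample(1:5, 1)
    t <- if (k > 0) sample(0:(2^k - 1), 1) else 0
    u <- expand_units(splitting_spec(k = k, P = P, t = t))
    expect_equal(nrow(u), P * 2^k - t)
    expect_identical(u$leg_pair,
                     (u$primary_segment - 1L) * as.integer(2^k) +
                       u$offset - as.integer(t))
  }
})

test_that("truncation is monotone: t+1 drops exactly the anterior-most unit", {
  for (t in 0:14) {
    a <- expand_units(splitting_spec(k = 4, P = 2, t = t))
    b <- expand_units(splitting_spec(k = 4, P = 2, t = t + 1))
    expect_equal(nrow(b), nrow(a) - 1)
    # unit formerly at leg pair j+1 now sits at j, same grid coordinates
    expect_equal(b[, c("primary_segment", "offset")],
                 a[-1, c("primary_segment", "offset")],
                 ignore_attr = TRUE)
  }
  expect_error(splitting_spec(k = 2, P = 2, t = 4), "must be < 2\\^k")
})

test_that("markers reproduce the normal julidan gonopod pattern", {
  sp <- splitting_spec(k = 4, P = 2, t = 5,
                       markers = list(marker_placement(1, dyadic_node(3, 6))),
                       anterior_marker_positions = 8)
  u <- apply_markers(expand_units(sp), sp)
  expect_equal(u$state_left[u$leg_pair == 8], "ANTERIOR_GONOPOD")
  expect_equal(u$state_right[u$leg_pair == 9], "POSTERIOR_GONOPOD")
  expect_true(all(u$state_left[!u$leg_pair %in% c(8, 9)] == "WALKING_LEG"))
})

test_that("markers on the posterior quarter of two modules give the homeotic pattern", {
  sp <- splitting_spec(k = 4, P = 2, t = 5,
                       markers = list(marker_placement(1, dyadic_node(2, 3)),
                                      marker_placement(2, dyadic_node(2, 3))),
                       anterior_marker_positions = 8)
  u <- apply_markers(expand_units(sp), sp)
  gon <- u$leg_pair[u$state_left %in%
                      c("ANTERIOR_GONOPOD", "POSTERIOR_GONOPOD")]
  expect_equal(gon, c(8:11, 24:27))
  expect_equal(u$state_left[u$leg_pair == 8], "ANTERIOR_GONOPOD")
  expect_true(all(u$state_left[u$leg_pair %in% c(9:11, 24:27)] ==
                    "POSTERIOR_GONOPOD"))
})

test_that("polydesmidan profile collapses gonopods to the generic type", {
  sp <- splitting_spec(k = 2, P = 4, t = 0,
                       markers = lapply(1:3, function(m)
                         marker_placement(m, dyadic_node(2, 3))),
                       taxon_profile = "polydesmidan")
  u <- apply_markers(expand_units(sp), sp)
  gon <- u$leg_pair[u$state_left == "GONOPOD_GENERIC"]
  expect_equal(gon, c(4, 8, 12))
  expect_false(any(u$state_left %in%
                     c("ANTERIOR_GONOPOD", "POSTERIOR_GONOPOD")))
})

test_that("empty marker list leaves every unit a walking leg", {
  sp <- splitting_spec(k = 3, P = 2, t = 1)
  u <- apply_markers(expand_units(sp), sp)
  expect_true(all(u$state_left == "WALKING_LEG"))
})

test_that("a marker entirely inside the truncated region warns, not errors", {
  sp <- splitting_spec(k = 4, P = 2, t = 5,
                       markers = list(marker_placement(1, dyadic_node(2, 0))))
  expect_warning(u <- apply_markers(expand_units(sp), sp),
                 "no phenotypic effect")
  expect_true(all(u$state_left == "WALKING_LEG"))
})

test_that("marked sets of consecutive primary segments are translates by 2^k", {
  set.seed(97)
  for (rep in 1:25) {
    k <- sample(1:5, 1)
    d <- sample(1:k, 1)
    node <- dyadic_node(d, sample(0:(2^d - 1), 1))
    m <- sample(1:3, 1)
    t <- sample(0:(2^k - 1), 1)
    sp <- function(ps) splitting_spec(k = k, P = 4, t = t,
                                      markers = list(marker_placement(ps, node)))
    g <- function(ps) {
      s <- sp(ps)
      u <- suppressWarnings(apply_markers(expand_units(s), s))
      u$leg_pair[u$state_left == "POSTERIOR_GONOPOD"]
    }
    a <- g(m); b <- g(m + 1)
    if (length(a) == 2^(k - d))  # marker of module m fully realized
      expect_identical(b, a + as.integer(2^k))
  }
})

test_that("anterior override is idempotent and independent of marker order", {
  mk <- list(marker_placement(1, dyadic_node(2, 3)),
             marker_placement(2, dyadic_node(2, 3)))
  sp1 <- splitting_spec(k = 4, P = 2, t = 5, markers = mk,
                        anterior_marker_positions = 8)
  sp2 <- splitting_spec(k = 4, P = 2, t = 5, markers = rev(mk),
                        anterior_marker_positions = 8)
  u1 <- apply_markers(expand_units(sp1), sp1)
  u2 <- apply_markers(expand_units(sp2), sp2)
  expect_identical(u1, u2)
  # re-applying the anterior override changes nothing
  u3 <- apply_markers(u1, splitting_spec(k = 4, P = 2, t = 5,
                                         anterior_marker_positions = 8))
  expect_identical(u3, u1)
})

test_that("simulate_phenotype composes expansion, markers, and the ring map", {
  normal <- splitting_spec(k = 4, P = 2, t = 5,
                           markers = list(marker_placement(1, dyadic_node(3, 6))),
                           anterior_marker_positions = 8)
  ph <- simulate_phenotype(normal)
  rings <- unique(vapply(gonopod_positions(ph), function(j)
    leg_pair_to_ring(j, ph$ring_map)[["comparative"]], integer(1)))
  expect_equal(rings, 7)

  homeotic <- splitting_spec(k = 4, P = 2, t = 5,
                             markers = list(marker_placement(1, dyadic_node(2, 3)),
                                            marker_placement(2, dyadic_node(2, 3))),
                             anterior_marker_positions = 8)
  ph2 <- simulate_phenotype(homeotic)
  rings2 <- sort(unique(vapply(gonopod_positions(ph2), function(j)
    leg_pair_to_ring(j, ph2$ring_map)[["comparative"]], integer(1))))
  expect_equal(rings2, c(7, 8, 15, 16))

  # degenerate but legal: one unit
  ph3 <- simulate_phenotype(splitting_spec(k = 0, P = 1, t = 0))
  expect_equal(nrow(ph3$units), 1)
})

test_that("splitting specs round-trip through JSON with validation", {
  sp <- splitting_spec(k = 4, P = 2, t = 5,
                       markers = list(marker_placement(1, dyadic_node(2, 3)),
                                      marker_placement(2, dyadic_node(2, 3))),
                       anterior_marker_positions = 8)
  path <- withr::local_tempfile(fileext = ".json")
  write_splitting_spec(sp, path)
  sp2 <- read_splitting_spec(path)
  expect_equal(sp2, sp)

  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"taxon_profile": "julidan", "k": 4, "P": 2}', bad)
  expect_error(read_splitting_spec(bad), "missing field")
  writeLines('{"taxon_profile": "weird", "k": 4, "P": 2, "t": 5}', bad)
  expect_error(read_splitting_spec(bad), "taxon_profile")
  writeLines('{"taxon_profile": "julidan", "k": 2, "P": 2, "t": 4}', bad)
  expect_error(read_splitting_spec(bad), "must be < 2\\^k")
})
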