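#' Gonopod-bearing positions of a phenotype
#'
#' @param ph A [phenotype()].
#' @param bilateral_only If `TRUE`, a position counts only when both sides
#'   are gonopods; by default either side suffices (two of the literature
#'   cases are unilateral).
#' @param baseline Optional integer vector of positions to exclude (e.g.
#'   the normal gonopod pair when scoring only the ectopic pattern).
#' @return Sorted integer vector of leg-pair positions whose state (on the
#'   relevant side(s)) is any gonopod type, anterior gonopods included.
#' @export
gonopod_positions <- function(ph, bilateral_only = FALSE, baseline = NULL) {
  stopifnot(inherits(ph, "phenotype"))
  u <- ph$units
  l <- u$state_left %in% GONOPOD_STATES
  r <- u$state_right %in% GONOPOD_STATES
  sel <- if (bilateral_only) l & r else l | r
  g <- sort(u$leg_pair[sel])
  if (!is.null(baseline)) g <- setdiff(g, as.integer(baseline))
  as.integer(g)
}

#' Decompose a position set into maximal contiguous runs
#'
#' @param G Sorted vector of positive integer positions (duplicates are
#'   dropped). An empty set gives an empty decomposition, not an error.
#' @return An object of class `"run_decomposition"`: list with `runs` (a
#'   two-column matrix `start`, `end` of maximal contiguous intervals) and
#'   `spacings` (differences between consecutive run starts).
#' @examples
#' decompose_runs(c(8:11, 24:27))   # runs [8,11], [24,27]; spacing 16
#' decompose_runs(c(4, 8, 12))      # three singletons; spacings 4, 4
#' @export
decompose_runs <- function(G) {
  G <- sort(unique(as.integer(G)))
  if (length(G) && any(G < 1L))
    stop("positions must be positive integers", call. = FALSE)
  if (!length(G)) {
    out <- list(runs = matrix(integer(), ncol = 2,
                              dimnames = list(NULL, c("start", "end"))),
                spacings = integer())
    return(structure(out, class = "run_decomposition"))
  }
  brk <- which(diff(G) > 1L)
  starts <- G[c(1L, brk + 1L)]
  ends <- G[c(brk, length(G))]
  structure(list(runs = cbind(start = starts, end = ends),
                 spacings = diff(starts)),
            class = "run_decomposition")
}

#' @export
print.run_decomposition <- function(x, ...) {
  n <- nrow(x$runs)
  cat(sprintf("Run decomposition: %d run%s\n", n, if (n == 1) "" else "s"))
  if (n) {
    cat(" ", paste(sprintf("[%d,%d]", x$runs[, "start"], x$runs[, "end"]),
                   collapse = " "), "\n")
    if (length(x$spacings))
      cat("  run-start spacings:", paste(x$spacings, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Infer the splitting-cycle count from run spacings
#'
#' If all spacings between consecutive run starts equal a common value `m`
#' and `m` is a power of 2, the estimated number of binary splitting cycles
#' is `log2(m)`; otherwise the estimate is undefined, with a reason.
#'
#' @param decomp A [decompose_runs()] result (or a raw position vector).
#' @return List with `defined` (logical), `k` (integer or `NA`), and
#'   `reason` (`""`, `"no spacings"`, `"unequal spacings"`, or
#'   `"not a power of 2"`).
#' @examples
#' infer_cycles(decompose_runs(c(8:11, 24:27)))$k   # 4
#' infer_cycles(decompose_runs(c(4, 8, 12)))$k      # 2
#' @export
infer_cycles <- function(decomp) {
  if (!inherits(decomp, "run_decomposition"))
    decomp <- decompose_runs(decomp)
  s <- decomp$spacings
  if (!length(s))
    return(list(defined = FALSE, k = NA_integer_, reason = "no spacings"))
  if (length(unique(s)) > 1L)
    return(list(defined = FALSE, k = NA_integer_,
                reason = "unequal spacings"))
  m <- s[1]
  if (bitwAnd(m, m - 1L) != 0L)
    return(list(defined = FALSE, k = NA_integer_,
                reason = "not a power of 2"))
  list(defined = TRUE, k = as.integer(round(log2(m))), reason = "")
}

# regenerate the position set of one anchored (node, block) marker event
.event_positions <- function(t, node, block, k) {
  iv <- leaf_interval(node, k)
  w <- as.integer(2^k)
  unlist(lapply(block[1]:block[2], function(m)
    (m - 1L) * w + iv[["lo"]]:iv[["hi"]] - t))
}

# exact feasibility scan: all candidate (t, node, block) triples whose
# regenerated set equals G, using the offset-set criterion
.scan_exact <- function(G, k, anchors) {
  w <- as.integer(2^k)
  cands <- list()
  for (t in anchors) {
    m <- (G + t - 1L) %/% w + 1L
    o <- (G + t - 1L) %% w + 1L
    mods <- sort(unique(m))
    if (!all(diff(mods) == 1L)) next           # occupied block not contiguous
    offs <- split(o, m)
    key <- sort(offs[[1]])
    if (length(offs) > 1L &&
        !all(vapply(offs[-1], function(x) identical(sort(x), key),
                    logical(1)))) next          # offset sets differ
    if (any(duplicated(key)) || !all(diff(key) == 1L)) next
    node <- .node_for_interval(min(key), max(key), k)
    if (is.null(node)) next                     # not a single dyadic node
    cands[[length(cands) + 1L]] <-
      list(t = t, node = node, block = c(mods[1], mods[length(mods)]),
           mismatch = integer())
  }
  cands
}

# tolerance scan: exhaustive over (t, node, block), by symmetric difference
.scan_tolerant <- function(G, k, anchors, max_mismatch) {
  w <- as.integer(2^k)
  Mmax <- (max(G) + max(anchors) - 1L) %/% w + 1L
  cands <- list()
  for (t in anchors) for (d in 0:k) for (i in 0:(2L^d - 1L)) {
    node <- dyadic_node(d, i)
    for (mlo in 1:Mmax) for (mhi in mlo:Mmax) {
      pos <- .event_positions(t, node, c(mlo, mhi), k)
      if (any(pos < 1L)) next
      mis <- c(setdiff(G, pos), setdiff(pos, G))
      if (length(mis) <= max_mismatch)
        cands[[length(cands) + 1L]] <-
          list(t = t, node = node, block = c(mlo, mhi),
               mismatch = sort(mis))
    }
  }
  cands
}

# minimal number of anchored (node, block) events whose union is exactly G.
# For each anchor only inclusion-maximal events are enumerated: a node whose
# leaf interval is contained in a module's observed offset set, extended over
# the maximal contiguous module range where that holds (any smaller event is
# a subset of a maximal one, so maximal events suffice for a minimal cover).
.min_event_cover <- function(G, k, anchors) {
  w <- as.integer(2^k)
  best <- length(G)  # singleton leaves cover position by position
  for (t in anchors) {
    m <- (G + t - 1L) %/% w + 1L
    o <- (G + t - 1L) %% w + 1L
    mrange <- min(m):max(m)      # unoccupied modules break event blocks
    offs <- lapply(mrange, function(mm) sort(o[m == mm]))
    events <- list()
    for (d in 0:k) for (i in seq_len(2^d) - 1L) {
      iv <- leaf_interval(dyadic_node(d, i), k)
      span <- iv[["lo"]]:iv[["hi"]]
      ok <- vapply(offs, function(s) all(span %in% s), logical(1))
      # truncated module: event must not reach below position 1
      ok <- ok & (mrange > 1L | iv[["lo"]] > t)
      if (!any(ok)) next
      r <- rle(ok)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (j in which(r$values)) {
        pos <- unlist(lapply(mrange[starts[j]:ends[j]], function(mm)
          (mm - 1L) * w + span - t))
        events[[length(events) + 1L]] <- pos
      }
    }
    if (!length(events)) next
    events <- unique(events)
    dfs <- function(uncovered, depth) {
      if (!length(uncovered)) return(depth)
      if (depth + 1L >= best) return(Inf)
      p <- uncovered[1]
      r <- Inf
      for (e in events) if (p %in% e)
        r <- min(r, dfs(setdiff(uncovered, e), depth + 1L))
      r
    }
    v <- dfs(G, 0L)
    if (v < best) best <- v
  }
  as.integer(best)
}

#' Fit the dyadic multiplicative model to a gonopod position set
#'
#' Exhaustive search for a single early-marker event explaining the
#' observed positions: an anchor `t` in `[0, 2^k)` (anterior truncation,
#' identifying the splitting grid's registration against the leg-pair
#' axis), a dyadic node, and a contiguous block of primary segments, such
#' that regenerating the pattern through the splitting model reproduces the
#' observed set exactly. For each anchor, positions map to module
#' `m = (p + t - 1) %/% 2^k + 1` and offset `o = (p + t - 1) %% 2^k + 1`;
#' the fit is feasible iff all occupied modules carry one identical offset
#' set, that set is the leaf interval of a single node, and the occupied
#' modules are contiguous.
#'
#' Among feasible fits the node of minimal depth is preferred (the most
#' parsimonious single marker), then the most posterior node (largest
#' index, reflecting inheritance by a posterior subset of the splitting
#' products), then the smallest anchor. When `anchor` is supplied the
#' search is restricted to that registration, which is how a taxon-default
#' grid (julidan `t = 5`, polydesmidan `t = 0`) is imposed.
#'
#' `multiplicative_cost` is 1 for a feasible single-event fit, otherwise
#' the minimal number of anchored (node, block) marker events whose union
#' is exactly the observed set. `sequential_cost` is the number of maximal
#' contiguous runs, the most charitable reading of a sequential
#' (segment-by-segment) determination model.
#'
#' @param G Non-empty vector of gonopod positions (or a [phenotype()]).
#' @param k Number of splitting cycles to fit under (>= 0).
#' @param anchor Optional fixed anchor in `[0, 2^k)`.
#' @param max_mismatch Tolerated number of mismatched positions (symmetric
#'   difference) for a "feasible" fit; default 0 (exact), as the pattern
#'   argument is exact.
#' @param compute_cost If `FALSE`, skip the minimal-event-cover search for
#'   infeasible fits (`multiplicative_cost` is then `NA`); the cover search
#'   is exact but combinatorial, so bulk classification turns it off.
#' @return An object of class `"dyadic_fit"`; see Details. Methods:
#'   `print`, `summary`, `coef`, `predict` (regenerated position set),
#'   `residuals` (mismatched positions).
#' @examples
#' fit <- dyadic_fit(c(8:11, 24:27), k = 4)
#' fit$anchor          # 5
#' fit$node            # node (2,3): posterior quarter
#' fit$block           # primary segments 1..2
#' @export
dyadic_fit <- function(G, k, anchor = NULL, max_mismatch = 0L,
                       compute_cost = TRUE) {
  if (inherits(G, "phenotype")) G <- gonopod_positions(G)
  G <- sort(unique(as.integer(G)))
  if (!length(G)) stop("'G' must be non-empty", call. = FALSE)
  if (any(G < 1L)) stop("positions must be >= 1", call. = FALSE)
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 0L)
    stop("'k' must be a single integer >= 0", call. = FALSE)
  anchors <- if (is.null(anchor)) 0:(as.integer(2^k) - 1L) else {
    anchor <- as.integer(anchor)
    if (anchor < 0L || anchor >= 2L^k)
      stop(sprintf("'anchor' must lie in [0, 2^k) = [0, %d)", 2L^k),
           call. = FALSE)
    anchor
  }
  decomp <- decompose_runs(G)

  cands <- if (max_mismatch == 0L) .scan_exact(G, k, anchors)
           else .scan_tolerant(G, k, anchors, max_mismatch)

  res <- list(G = G, k = k, decomposition = decomp,
              sequential_cost = nrow(decomp$runs))
  if (length(cands)) {
    ord <- order(vapply(cands, function(c) length(c$mismatch), integer(1)),
                 vapply(cands, function(c) c$node$depth, integer(1)),
                 -vapply(cands, function(c) c$node$index, integer(1)),
                 vapply(cands, function(c) c$t, integer(1)))
    b <- cands[[ord[1]]]
    regen <- sort(.event_positions(b$t, b$node, b$block, k))
    if (max_mismatch == 0L && !identical(regen, G))
      stop("internal error: feasible fit failed to regenerate G")  # soundness
    res <- c(res, list(feasible = TRUE, anchor = b$t, node = b$node,
                       block = b$block, multiplicative_cost = 1L,
                       regenerated = regen, mismatch = b$mismatch,
                       informative = b$block[2] > b$block[1] &&
                         nrow(decomp$runs) >= 2L))
  } else {
    res <- c(res, list(feasible = FALSE, anchor = NA_integer_, node = NULL,
                       block = c(NA_integer_, NA_integer_),
                       multiplicative_cost = if (compute_cost)
                         .min_event_cover(G, k, anchors) else NA_integer_,
                       regenerated = integer(), mismatch = G,
                       informative = FALSE))
  }
  structure(res, class = "dyadic_fit")
}

#' @export
print.dyadic_fit <- function(x, ...) {
  cat(sprintf("Dyadic multiplicative fit, k = %d (module width %d)\n",
              x$k, 2^x$k))
  cat("  positions:", paste(x$G, collapse = ", "), "\n")
  if (x$feasible) {
    cat(sprintf("  feasible single marker event: anchor t = %d, node %s (offsets %d..%d), primary segments %d..%d\n",
                x$anchor, format(x$node),
                leaf_interval(x$node, x$k)[["lo"]],
                leaf_interval(x$node, x$k)[["hi"]],
                x$block[1], x$block[2]))
    if (!x$informative)
      cat("  single block only: contiguous extension, multiplicative model not required\n")
  } else {
    cat("  no single-event fit at this k\n")
  }
  cat(sprintf("  parsimony: multiplicative cost %d, sequential cost %d\n",
              x$multiplicative_cost, x$sequential_cost))
  invisible(x)
}

#' @export
summary.dyadic_fit <- function(object, ...) {
  print(object)
  print(object$decomposition)
  invisible(object)
}

#' @export
coef.dyadic_fit <- function(object, ...) {
  c(k = object$k, anchor = object$anchor,
    depth = if (object$feasible) object$node$depth else NA_integer_,
    index = if (object$feasible) object$node$index else NA_integer_,
    block_lo = object$block[1], block_hi = object$block[2])
}

#' @export
predict.dyadic_fit <- function(object, ...) object$regenerated

#' @export
residuals.dyadic_fit <- function(object, ...) {
  list(missed = setdiff(object$G, object$regenerated),
       unexplained = setdiff(object$regenerated, object$G))
}

#' Compare the multiplicative and sequential segmentation models
#'
#' Runs [dyadic_fit()] over a range of splitting-cycle counts and reports
#' whether the observed gonopod pattern is explainable as a single early
#' marker event under the multiplicative model, against the sequential
#' null in which each contiguous run is an independent marker event.
#'
#' Verdicts: `"multiplicative-consistent"` (some `k` admits a feasible
#' single-event fit spanning more than one primary segment, and the run
#' spacing is a power of 2); `"contiguous-anomaly"` (two or more runs, no
#' such fit at any `k`); `"uninformative-one-run"` (a single contiguous
#' run fits trivially within one module at any `k` — a contiguous
#' extension of the normal pattern, for which the multiplicative model is
#' not required); `"no-gonopods"`.
#'
#' @param ph A [phenotype()] or a raw position vector.
#' @param k_range Splitting-cycle counts to try (default `1:6`).
#' @param bilateral_only,baseline Passed to [gonopod_positions()].
#' @param compute_cost Passed to [dyadic_fit()].
#' @return An object of class `"model_comparison"`: list with `G`,
#'   `decomposition`, `k_hat` (from [infer_cycles()]), `fits` (one
#'   [dyadic_fit()] per `k`), `table` (per-`k` summary data frame),
#'   `consistent_k` (the `k` values with an informative feasible fit),
#'   `verdict`, and `diff` (mismatch of the regenerated pattern at the
#'   best `k`; empty when feasible).
#' @examples
#' cmp <- compare_models(fixtures()$homeotic_ommatoiulus)
#' cmp$verdict         # "multiplicative-consistent"
#' cmp$consistent_k    # 4
#' @export
compare_models <- function(ph, k_range = 1:6, bilateral_only = FALSE,
                           baseline = NULL, compute_cost = TRUE) {
  G <- if (inherits(ph, "phenotype"))
    gonopod_positions(ph, bilateral_only = bilateral_only,
                      baseline = baseline)
  else sort(unique(as.integer(ph)))
  decomp <- decompose_runs(G)
  n_runs <- nrow(decomp$runs)
  kh <- infer_cycles(decomp)

  if (!length(G)) {
    out <- list(G = G, decomposition = decomp, k_hat = kh, fits = list(),
                table = NULL, consistent_k = integer(),
                verdict = "no-gonopods", diff = integer())
    return(structure(out, class = "model_comparison"))
  }

  fits <- lapply(k_range, function(k)
    dyadic_fit(G, k, compute_cost = compute_cost))
  names(fits) <- as.character(k_range)
  tab <- data.frame(
    k = as.integer(k_range),
    feasible = vapply(fits, `[[`, logical(1), "feasible"),
    informative = vapply(fits, `[[`, logical(1), "informative"),
    anchor = vapply(fits, `[[`, integer(1), "anchor"),
    depth = vapply(fits, function(f)
      if (f$feasible) f$node$depth else NA_integer_, integer(1)),
    index = vapply(fits, function(f)
      if (f$feasible) f$node$index else NA_integer_, integer(1)),
    block_lo = vapply(fits, function(f) f$block[1], integer(1)),
    block_hi = vapply(fits, function(f) f$block[2], integer(1)),
    multiplicative_cost = vapply(fits, `[[`, integer(1),
                                 "multiplicative_cost"),
    sequential_cost = vapply(fits, `[[`, integer(1), "sequential_cost"),
    row.names = NULL)

  consistent_k <- tab$k[tab$feasible & tab$informative]
  verdict <- if (n_runs == 1L) "uninformative-one-run"
    else if (length(consistent_k) && kh$defined) "multiplicative-consistent"
    else "contiguous-anomaly"
  diff <- if (length(consistent_k))
    fits[[as.character(consistent_k[1])]]$mismatch else G

  structure(list(G = G, decomposition = decomp, k_hat = kh, fits = fits,
                 table = tab, consistent_k = consistent_k,
                 verdict = verdict, diff = diff),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison: multiplicative (single early marker) vs sequential\n")
  cat("  gonopod positions:", paste(x$G, collapse = ", "), "\n")
  print(x$decomposition)
  if (x$k_hat$defined)
    cat(sprintf("  inferred splitting cycles from spacing: k = %d\n",
                x$k_hat$k))
  else cat(sprintf("  splitting cycles undefined (%s)\n", x$k_hat$reason))
  if (!is.null(x$table)) print(x$table, row.names = FALSE)
  cat("  verdict:", x$verdict, "\n")
  if (x$verdict == "uninformative-one-run")
    cat("  (contiguous extension; multiplicative model not required)\n")
  invisible(x)
}

#' @export
summary.model_comparison <- function(object, ...) {
  print(object)
  if (length(object$consistent_k))
    cat("  consistent at k =", paste(object$consistent_k, collapse = ", "),
        "; regenerated-pattern mismatch:",
        if (length(object$diff)) paste(object$diff, collapse = ", ")
        else "none", "\n")
  invisible(object)
}
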