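#' Build the dorsal ring map for a trunk of L leg pairs
#'
#' Standard millipede trunk layout: ring 1 is the legless collum; rings 2-4
#' (haplosegmental) carry one leg pair each (pairs 1-3); every later ring is
#' a diplosegment with two leg pairs, comparative ring `r >= 5` carrying
#' pairs `2r - 6` and `2r - 5`. A trailing odd leg pair, if any, occupies a
#' final one-pair ring flagged `"incomplete"`.
#'
#' Fusion anomalies merge two adjacent diplosegment positions into a single
#' physical ring carrying four leg pairs. Two numberings are carried
#' throughout: the comparative index (normal-specimen-equivalent) and the
#' physical index (count along the actual animal); they differ only distal
#' to a fusion.
#'
#' @param L Number of leg pairs (>= 1; trunks shorter than the three
#'   haplosegmental pairs are degenerate but legal).
#' @param fusions List of length-2 vectors of adjacent comparative ring
#'   indices (`>= 5`) to merge, e.g. `list(c(13, 14))`.
#' @return An object of class `"ring_map"`: list with elements `table`
#'   (one row per comparative ring: `comparative_index`, `physical_index`,
#'   `leg_pairs` comma-joined, `flags`), `L`, and `fusions`.
#' @examples
#' rm27 <- build_ring_map(27)
#' ring_to_leg_pairs(7, rm27)    # 8 9  (the gonopod-bearing ring)
#' rmf <- build_ring_map(27, fusions = list(c(13, 14)))
#' ring_to_leg_pairs(13, rmf, numbering = "physical")  # 20 21 22 23
#' @export
build_ring_map <- function(L, fusions = NULL) {
  L <- as.integer(L)
  if (length(L) != 1L || is.na(L) || L < 1L)
    stop("'L' must be a single integer >= 1", call. = FALSE)
  n_haplo <- min(L, 3L)        # degenerate short trunks stay legal
  n_rings <- 1L + n_haplo + ceiling(max(L - 3L, 0L) / 2)
  pairs <- vector("list", n_rings)
  flags <- character(n_rings)
  pairs[[1]] <- integer()
  flags[1] <- "collum"
  for (r in 1 + seq_len(n_haplo)) {
    pairs[[r]] <- r - 1L
    flags[r] <- "haplosegment"
  }
  if (n_rings >= 5L) for (r in 5:n_rings) {
    p <- c(2L * r - 6L, 2L * r - 5L)
    p <- p[p <= L]
    pairs[[r]] <- p
    flags[r] <- if (length(p) == 1L) "incomplete" else ""
  }

  if (is.null(fusions)) fusions <- list()
  if (is.numeric(fusions) && length(fusions) == 2L) fusions <- list(fusions)
  fusions <- lapply(fusions, as.integer)
  seen <- integer()
  for (f in fusions) {
    if (length(f) != 2L || f[2] != f[1] + 1L)
      stop("each fusion must name two adjacent comparative rings",
           call. = FALSE)
    if (f[1] < 5L)
      stop(sprintf(
        "fusion (%d,%d) touches the collum or a haplosegmental ring; only diplosegments may fuse",
        f[1], f[2]), call. = FALSE)
    if (f[2] > n_rings)
      stop(sprintf("fusion ring %d exceeds the ring count %d", f[2], n_rings),
           call. = FALSE)
    if (any(f %in% seen))
      stop("fusion intervals overlap", call. = FALSE)
    seen <- c(seen, f)
  }

  # physical index: the second member of a fused pair shares its partner's
  # physical ring, and everything distal shifts back by one per fusion
  second <- vapply(fusions, `[`, integer(1), 2L)
  physical <- integer(n_rings)
  phys <- 0L
  for (r in seq_len(n_rings)) {
    if (!(r %in% second)) phys <- phys + 1L
    physical[r] <- phys
  }
  fused_flag <- ifelse(seq_len(n_rings) %in% unlist(fusions), "fused", "")
  flags <- trimws(paste(flags, fused_flag))

  tab <- data.frame(
    comparative_index = seq_len(n_rings),
    physical_index = physical,
    leg_pairs = vapply(pairs, paste, character(1), collapse = ","),
    flags = flags,
    stringsAsFactors = FALSE)
  structure(list(table = tab, L = L, fusions = fusions), class = "ring_map")
}

.ring_pairs <- function(ring_map, r) {
  s <- ring_map$table$leg_pairs[ring_map$table$comparative_index == r]
  if (!length(s) || !nzchar(s)) integer() else as.integer(strsplit(s, ",")[[1]])
}

#' Map a leg pair to its dorsal ring
#'
#' @param j Leg-pair index in `[1, L]`.
#' @param ring_map A [build_ring_map()] object.
#' @return Named integer vector `c(comparative, physical)`.
#' @examples
#' leg_pair_to_ring(8, build_ring_map(27))    # comparative 7, physical 7
#' @export
leg_pair_to_ring <- function(j, ring_map) {
  stopifnot(inherits(ring_map, "ring_map"))
  j <- as.integer(j)
  if (length(j) != 1L || is.na(j) || j < 1L || j > ring_map$L)
    stop(sprintf("leg pair index must lie in [1, %d]", ring_map$L),
         call. = FALSE)
  r <- if (j <= 3L) j + 1L else (j + 6L) %/% 2L
  c(comparative = r,
    physical = ring_map$table$physical_index[
      ring_map$table$comparative_index == r])
}

#' Leg pairs carried by a ring
#'
#' Inverse of [leg_pair_to_ring()]. Under comparative numbering a fused ring
#' is still addressed by either of its constituent comparative indices (each
#' returning its own two pairs); under physical numbering the merged ring
#' returns all four.
#'
#' @param r Ring index.
#' @param ring_map A [build_ring_map()] object.
#' @param numbering `"comparative"` (default) or `"physical"`.
#' @return Integer vector of leg-pair indices (empty for the collum).
#' @export
ring_to_leg_pairs <- function(r, ring_map,
                              numbering = c("comparative", "physical")) {
  stopifnot(inherits(ring_map, "ring_map"))
  numbering <- match.arg(numbering)
  r <- as.integer(r)
  tab <- ring_map$table
  if (numbering == "comparative") {
    if (length(r) != 1L || is.na(r) || !r %in% tab$comparative_index)
      stop(sprintf("invalid comparative ring index %s", r), call. = FALSE)
    .ring_pairs(ring_map, r)
  } else {
    if (length(r) != 1L || is.na(r) || !r %in% tab$physical_index)
      stop(sprintf("invalid physical ring index %s", r), call. = FALSE)
    rows <- tab$comparative_index[tab$physical_index == r]
    sort(unlist(lapply(rows, .ring_pairs, ring_map = ring_map)))
  }
}

#' @export
print.ring_map <- function(x, ...) {
  nf <- length(x$fusions)
  cat(sprintf("Ring map: %d leg pairs, %d comparative rings, %d physical rings%s\n",
              x$L, nrow(x$table), max(x$table$physical_index),
              if (nf) sprintf(" (%d fusion%s)", nf, if (nf > 1) "s" else "")
              else ""))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Read / write a ring map as TSV
#'
#' Columns: `comparative_index`, `physical_index`, `leg_pairs`
#' (comma-joined), `flags`.
#'
#' @param ring_map A [build_ring_map()] object.
#' @param path File path.
#' @export
write_ring_map <- function(ring_map, path) {
  stopifnot(inherits(ring_map, "ring_map"))
  utils::write.table(ring_map$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
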