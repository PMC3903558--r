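#' Expand primary segments into ventral units
#'
#' Runs the splitting grid: each of the `P` primary segments is subdivided
#' through `k` binary splitting cycles into `2^k` ventral units; the anterior
#' `t` virtual positions of primary segment 1 are dropped. Global leg-pair
#' indices are 1-based and exclude the collum, so
#' `leg_pair = (primary_segment - 1) * 2^k + offset - t`.
#'
#' @param spec A [splitting_spec()].
#' @return A data frame of `L = P * 2^k - t` rows with columns `leg_pair`,
#'   `primary_segment`, `offset` (1-based within-module), `state_left`,
#'   `state_right` (all initialized to `"WALKING_LEG"`) and `annotation`.
#' @examples
#' u <- expand_units(splitting_spec(k = 4, P = 2, t = 5))
#' nrow(u)                      # 27
#' u[u$leg_pair == 8, c("primary_segment", "offset")]   # module 1, offset 13
#' @export
expand_units <- function(spec) {
  stopifnot(inherits(spec, "splitting_spec"))
  L <- spec$L
  g <- seq_len(L) + spec$t          # virtual grid position
  w <- as.integer(2^spec$k)
  data.frame(
    leg_pair = seq_len(L),
    primary_segment = (g - 1L) %/% w + 1L,
    offset = (g - 1L) %% w + 1L,
    state_left = rep("WALKING_LEG", L),
    state_right = rep("WALKING_LEG", L),
    annotation = rep("", L),
    stringsAsFactors = FALSE)
}

#' Apply positional markers to expanded units
#'
#' Early posterior-gonopod markers: for each [marker_placement()], every
#' realized unit of that primary segment whose offset lies in the node's
#' [leaf_interval()] becomes `POSTERIOR_GONOPOD` on both sides. The late
#' anterior marker is applied afterwards (it acts once segmentation of the
#' relevant trunk region is complete) and overrides its positions to
#' `ANTERIOR_GONOPOD`. Under the polydesmidan profile, which has a single
#' gonopod type, all gonopod states collapse to `GONOPOD_GENERIC`.
#'
#' A marker whose leaf block falls entirely in the truncated region has no
#' phenotypic effect; this raises a warning, not an error.
#'
#' @param units Data frame from [expand_units()].
#' @param spec The owning [splitting_spec()].
#' @return The units with states set.
#' @export
apply_markers <- function(units, spec) {
  stopifnot(inherits(spec, "splitting_spec"))
  for (m in spec$markers) {
    iv <- leaf_interval(m$node, spec$k)
    sel <- units$primary_segment == m$primary_segment &
      units$offset >= iv[["lo"]] & units$offset <= iv[["hi"]]
    if (!any(sel)) {
      warning(sprintf(
        "marker on primary segment %d, node %s lies entirely in the truncated region: no phenotypic effect",
        m$primary_segment, format(m$node)), call. = FALSE)
      next
    }
    units$state_left[sel] <- "POSTERIOR_GONOPOD"
    units$state_right[sel] <- "POSTERIOR_GONOPOD"
  }
  if (length(spec$anterior_marker_positions)) {
    sel <- units$leg_pair %in% spec$anterior_marker_positions
    units$state_left[sel] <- "ANTERIOR_GONOPOD"
    units$state_right[sel] <- "ANTERIOR_GONOPOD"
  }
  if (spec$taxon_profile == "polydesmidan") {
    for (col in c("state_left", "state_right")) {
      sel <- units[[col]] %in% GONOPOD_STATES
      units[[col]][sel] <- "GONOPOD_GENERIC"
    }
  }
  units
}

#' Simulate the phenotype predicted by a splitting specification
#'
#' Composition of [expand_units()], [apply_markers()] and
#' [build_ring_map()]: expands the splitting grid, writes marker-determined
#' appendage states, and attaches the taxon-default ring map (no fusions
#' unless given).
#'
#' @param spec A [splitting_spec()].
#' @param fusions Optional list of adjacent comparative ring index pairs to
#'   fuse, passed to [build_ring_map()].
#' @param provenance Free-text provenance stored on the phenotype.
#' @return A [phenotype()] object.
#' @examples
#' sp <- splitting_spec(k = 4, P = 2, t = 5,
#'                      markers = list(marker_placement(1, dyadic_node(3, 6))),
#'                      anterior_marker_positions = 8)
#' ph <- simulate_phenotype(sp)
#' gonopod_positions(ph)        # 8 9
#' @export
simulate_phenotype <- function(spec, fusions = NULL,
                               provenance = "simulated under the multiplicative model") {
  stopifnot(inherits(spec, "splitting_spec"))
  units <- apply_markers(expand_units(spec), spec)
  phenotype(units, taxon_profile = spec$taxon_profile,
            ring_map = build_ring_map(spec$L, fusions = fusions),
            provenance = provenance)
}

#' @rdname simulate_phenotype
#' @param object A [splitting_spec()] (method for [stats::simulate()]).
#' @param nsim Number of phenotypes to simulate (the model is deterministic,
#'   so all replicates are identical).
#' @param seed Ignored; accepted for generic compatibility.
#' @param ... Passed to [simulate_phenotype()].
#' @export
simulate.splitting_spec <- function(object, nsim = 1, seed = NULL, ...) {
  out <- replicate(nsim, simulate_phenotype(object, ...), simplify = FALSE)
  if (nsim == 1) out[[1]] else out
}
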