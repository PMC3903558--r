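# Appendage state vocabulary. ANTERIOR/POSTERIOR gonopods belong to the
# julidan profile (two gonopod types on ring 7); polydesmidans have a single
# gonopod type, GONOPOD_GENERIC.
APPENDAGE_STATES <- c("WALKING_LEG", "ANTERIOR_GONOPOD", "POSTERIOR_GONOPOD",
                      "GONOPOD_GENERIC", "ATROPHIED_LEG", "ABSENT")

GONOPOD_STATES <- c("ANTERIOR_GONOPOD", "POSTERIOR_GONOPOD", "GONOPOD_GENERIC")

TAXON_PROFILES <- c("julidan", "polydesmidan")

#' Placement of an early positional marker on the splitting tree
#'
#' The early posterior-gonopod marker is hypothesized to be present in a
#' primary segment before it splits, and to be inherited by the block of
#' definitive units addressed by a node of the splitting tree.
#'
#' @param primary_segment Integer >= 1: which primary segment carries the
#'   marker.
#' @param node A [dyadic_node()] (or a length-2 vector `c(depth, index)`)
#'   addressing the inherited block.
#' @param marker_kind Currently only `"posterior_gonopod"`.
#' @return An object of class `"marker_placement"`.
#' @export
marker_placement <- function(primary_segment, node,
                             marker_kind = "posterior_gonopod") {
  primary_segment <- as.integer(primary_segment)
  if (length(primary_segment) != 1L || is.na(primary_segment) ||
      primary_segment < 1L)
    stop("'primary_segment' must be a single integer >= 1", call. = FALSE)
  if (!inherits(node, "dyadic_node")) node <- dyadic_node(node[[1]], node[[2]])
  marker_kind <- match.arg(marker_kind, "posterior_gonopod")
  structure(list(primary_segment = primary_segment, node = node,
                 marker_kind = marker_kind),
            class = "marker_placement")
}

#' Specification of a multiplicative segmentation process
#'
#' Parameters of the generative model: `P` primary segments each expand
#' through `k` cycles of binary splitting into `2^k` ventral units (leg-pair
#' positions); the anterior `t` virtual positions of primary segment 1 are
#' never realized (anterior truncation), so the realized trunk carries
#' `L = P * 2^k - t` leg pairs. Early posterior-gonopod markers sit on nodes
#' of the splitting tree and are inherited by the corresponding leaf blocks;
#' the late anterior-gonopod marker is strictly localized to fixed leg-pair
#' positions and is applied after segmentation is complete.
#'
#' @param k Integer >= 0: binary splitting cycles per primary segment.
#' @param P Integer >= 1: number of realized primary segments.
#' @param t Integer in `[0, 2^k)`: anterior truncation, in virtual leg-pair
#'   positions of primary segment 1.
#' @param markers List of [marker_placement()] objects (early markers).
#' @param anterior_marker_positions Integer vector of global leg-pair indices
#'   carrying the late, strictly localized anterior-gonopod marker.
#' @param taxon_profile `"julidan"` (anterior + posterior gonopod types) or
#'   `"polydesmidan"` (single generic gonopod type).
#' @return An object of class `"splitting_spec"`.
#' @examples
#' # normal julidan male: early marker on the (3,6) node of primary segment 1
#' # (leg pairs 8-9), late anterior marker at pair 8
#' sp <- splitting_spec(k = 4, P = 2, t = 5,
#'                      markers = list(marker_placement(1, dyadic_node(3, 6))),
#'                      anterior_marker_positions = 8)
#' sp
#' @seealso [expand_units()], [apply_markers()], [simulate_phenotype()],
#'   [read_splitting_spec()]
#' @export
splitting_spec <- function(k, P, t = 0L, markers = list(),
                           anterior_marker_positions = integer(),
                           taxon_profile = c("julidan", "polydesmidan")) {
  k <- as.integer(k); P <- as.integer(P); t <- as.integer(t)
  taxon_profile <- match.arg(taxon_profile)
  if (length(k) != 1L || is.na(k) || k < 0L)
    stop("'k' must be a single integer >= 0", call. = FALSE)
  if (length(P) != 1L || is.na(P) || P < 1L)
    stop("'P' must be a single integer >= 1", call. = FALSE)
  if (length(t) != 1L || is.na(t) || t < 0L)
    stop("'t' must be a single integer >= 0", call. = FALSE)
  if (t >= 2L^k)
    stop(sprintf(
      "anterior truncation t = %d must be < 2^k = %d (truncation may never consume a whole primary segment)",
      t, 2L^k), call. = FALSE)
  if (inherits(markers, "marker_placement")) markers <- list(markers)
  markers <- lapply(markers, function(m) {
    if (!inherits(m, "marker_placement"))
      m <- marker_placement(m$primary_segment %||% m$ps,
                            dyadic_node(m$depth, m$index))
    m
  })
  for (m in markers) {
    if (m$primary_segment > P)
      stop(sprintf("marker on primary segment %d but P = %d",
                   m$primary_segment, P), call. = FALSE)
    leaf_interval(m$node, k)  # validates node depth against k
  }
  L <- P * as.integer(2^k) - t
  amp <- sort(unique(as.integer(anterior_marker_positions)))
  if (length(amp) && (any(amp < 1L) || any(amp > L)))
    stop(sprintf("anterior marker positions must lie in [1, L] = [1, %d]", L),
         call. = FALSE)
  structure(list(k = k, P = P, t = t, markers = markers,
                 anterior_marker_positions = amp,
                 taxon_profile = taxon_profile, L = L),
            class = "splitting_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.splitting_spec <- function(x, ...) {
  cat(sprintf("Multiplicative splitting specification (%s profile)\n",
              x$taxon_profile))
  cat(sprintf("  k = %d cycles -> %d units per primary segment\n", x$k, 2^x$k))
  cat(sprintf("  P = %d primary segments, anterior truncation t = %d\n",
              x$P, x$t))
  cat(sprintf("  realized leg pairs: L = P*2^k - t = %d\n", x$L))
  if (length(x$markers)) {
    cat("  early posterior-gonopod markers:\n")
    for (m in x$markers) {
      iv <- leaf_interval(m$node, x$k)
      cat(sprintf("    primary segment %d, node %s -> offsets %d..%d\n",
                  m$primary_segment, format(m$node), iv[["lo"]], iv[["hi"]]))
    }
  } else cat("  no early markers\n")
  if (length(x$anterior_marker_positions))
    cat("  late anterior marker at leg pair(s):",
        paste(x$anterior_marker_positions, collapse = ", "), "\n")
  invisible(x)
}

#' Read / write a splitting specification as JSON
#'
#' The on-disk format is a single JSON object, e.g.
#' `{"taxon_profile": "julidan", "k": 4, "P": 2, "t": 5,
#'   "markers": [{"ps": 1, "depth": 2, "index": 3}],
#'   "anterior_marker_positions": [8]}`.
#' All fields are validated on load; structural errors name the offending
#' field.
#'
#' @param path File path.
#' @param spec A [splitting_spec()] object.
#' @return `read_splitting_spec` returns a validated [splitting_spec()];
#'   `write_splitting_spec` invisibly returns `path`.
#' @export
read_splitting_spec <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = TRUE)
  req <- c("taxon_profile", "k", "P", "t")
  miss <- setdiff(req, names(obj))
  if (length(miss))
    stop("splitting-spec JSON missing field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!is.character(obj$taxon_profile) ||
      !obj$taxon_profile %in% TAXON_PROFILES)
    stop("'taxon_profile' must be one of: ",
         paste(TAXON_PROFILES, collapse = ", "), call. = FALSE)
  for (f in c("k", "P", "t")) {
    v <- obj[[f]]
    if (!is.numeric(v) || length(v) != 1L || v != round(v))
      stop(sprintf("field '%s' must be a single integer", f), call. = FALSE)
  }
  markers <- list()
  if (!is.null(obj$markers) && length(obj$markers)) {
    md <- obj$markers
    if (is.data.frame(md)) {
      if (!all(c("ps", "depth", "index") %in% names(md)))
        stop("each marker needs fields 'ps', 'depth', 'index'", call. = FALSE)
      markers <- lapply(seq_len(nrow(md)), function(i)
        marker_placement(md$ps[i], dyadic_node(md$depth[i], md$index[i])))
    } else {
      markers <- lapply(md, function(m) {
        if (!all(c("ps", "depth", "index") %in% names(m)))
          stop("each marker needs fields 'ps', 'depth', 'index'",
               call. = FALSE)
        marker_placement(m$ps, dyadic_node(m$depth, m$index))
      })
    }
  }
  splitting_spec(k = obj$k, P = obj$P, t = obj$t, markers = markers,
                 anterior_marker_positions =
                   as.integer(obj$anterior_marker_positions %||% integer()),
                 taxon_profile = obj$taxon_profile)
}

#' @rdname read_splitting_spec
#' @export
write_splitting_spec <- function(spec, path) {
  stopifnot(inherits(spec, "splitting_spec"))
  obj <- list(
    taxon_profile = spec$taxon_profile,
    k = spec$k, P = spec$P, t = spec$t,
    markers = lapply(spec$markers, function(m)
      list(ps = m$primary_segment, depth = m$node$depth,
           index = m$node$index)),
    anterior_marker_positions = as.integer(spec$anterior_marker_positions))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
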