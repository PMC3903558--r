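#' Dyadic node of a binary splitting tree
#'
#' A node of the binary splitting tree of one primary segment. At splitting
#' depth `d` the primary segment is divided into `2^d` blocks; the node
#' `(depth, index)` addresses the `index`-th block (0-based) at that depth.
#' After `k` cycles the leaves are the `2^k` definitive ventral units of the
#' module, and every node addresses a power-of-2 block of them.
#'
#' @param depth Integer >= 0, the splitting depth of the node.
#' @param index Integer in `[0, 2^depth)`, 0-based position at that depth.
#' @return An object of class `"dyadic_node"`: a list with elements `depth`
#'   and `index`.
#' @examples
#' dyadic_node(2, 3)            # posterior quarter of a module
#' leaf_interval(dyadic_node(2, 3), k = 4)   # offsets 13..16
#' @seealso [leaf_interval()]
#' @export
dyadic_node <- function(depth, index) {
  depth <- as.integer(depth)
  index <- as.integer(index)
  if (length(depth) != 1L || is.na(depth) || depth < 0L)
    stop("'depth' must be a single integer >= 0", call. = FALSE)
  if (length(index) != 1L || is.na(index) || index < 0L || index >= 2^depth)
    stop(sprintf("'index' must lie in [0, 2^depth) = [0, %d); got %d",
                 2^depth, index), call. = FALSE)
  structure(list(depth = depth, index = index), class = "dyadic_node")
}

#' @export
print.dyadic_node <- function(x, ...) {
  cat(sprintf("<dyadic node: depth %d, index %d>\n", x$depth, x$index))
  invisible(x)
}

#' @export
format.dyadic_node <- function(x, ...) sprintf("(%d,%d)", x$depth, x$index)

#' Leaf interval addressed by a dyadic node
#'
#' Maps a node of the splitting tree to the 1-based interval of within-module
#' offsets it covers after `k` splitting cycles. The width is
#' `2^(k - depth)`; at every depth the intervals of the `2^depth` nodes
#' partition `[1, 2^k]`.
#'
#' @param node A [dyadic_node()].
#' @param k Integer >= node depth; the number of splitting cycles of the
#'   owning specification.
#' @return Integer vector `c(lo, hi)` with `1 <= lo <= hi <= 2^k`.
#' @examples
#' leaf_interval(dyadic_node(0, 0), k = 4)   # whole module: 1..16
#' leaf_interval(dyadic_node(3, 6), k = 4)   # 13..14
#' @export
leaf_interval <- function(node, k) {
  if (!inherits(node, "dyadic_node")) node <- dyadic_node(node[[1]], node[[2]])
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 0L)
    stop("'k' must be a single integer >= 0", call. = FALSE)
  if (node$depth > k)
    stop(sprintf("node depth %d exceeds splitting cycles k = %d",
                 node$depth, k), call. = FALSE)
  w <- as.integer(2^(k - node$depth))
  lo <- node$index * w + 1L
  c(lo = lo, hi = lo + w - 1L)
}

# internal: node whose leaf interval is exactly offsets [lo, hi], or NULL
.node_for_interval <- function(lo, hi, k) {
  w <- hi - lo + 1L
  d <- k - round(log2(w))
  if (w < 1L || bitwAnd(w, w - 1L) != 0L || d < 0L) return(NULL)
  if ((lo - 1L) %% w != 0L) return(NULL)
  dyadic_node(d, (lo - 1L) %/% w)
}
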