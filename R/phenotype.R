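#' Construct a phenotype record
#'
#' The observable object: an ordered list of ventral units (leg-pair
#' positions with per-side appendage states) plus the dorsal ring map and
#' free-text provenance. Positions are 1-based and exclude the collum.
#'
#' @param units Data frame with columns `leg_pair`, `state_left`,
#'   `state_right` and optionally `annotation`, `primary_segment`, `offset`.
#'   Leg pairs must be contiguous from 1.
#' @param taxon_profile `"julidan"` or `"polydesmidan"`; controls which
#'   gonopod states are legal (anterior/posterior vs generic).
#' @param ring_map A [build_ring_map()] object covering exactly the units;
#'   built without fusions if omitted.
#' @param provenance Free text.
#' @param stadium,podous_rings Optional integer metadata.
#' @return An object of class `"phenotype"`.
#' @seealso [read_phenotype()], [fixtures()], [simulate_phenotype()]
#' @export
phenotype <- function(units, taxon_profile = c("julidan", "polydesmidan"),
                      ring_map = NULL, provenance = "",
                      stadium = NA_integer_, podous_rings = NA_integer_) {
  taxon_profile <- match.arg(taxon_profile)
  units <- as.data.frame(units, stringsAsFactors = FALSE)
  req <- c("leg_pair", "state_left", "state_right")
  miss <- setdiff(req, names(units))
  if (length(miss))
    stop("units lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"annotation" %in% names(units)) units$annotation <- ""
  units <- units[order(units$leg_pair), , drop = FALSE]
  rownames(units) <- NULL
  L <- nrow(units)
  if (L < 1L) stop("phenotype has no units", call. = FALSE)
  if (!identical(as.integer(units$leg_pair), seq_len(L)))
    stop("leg-pair indices must be contiguous from 1", call. = FALSE)
  for (col in c("state_left", "state_right")) {
    bad <- setdiff(unique(units[[col]]), APPENDAGE_STATES)
    if (length(bad))
      stop("unknown appendage state(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  both_absent <- units$state_left == "ABSENT" & units$state_right == "ABSENT"
  if (any(both_absent))
    stop("at least one side per unit must be non-ABSENT (violated at position ",
         paste(units$leg_pair[both_absent], collapse = ", "), ")",
         call. = FALSE)
  states <- c(units$state_left, units$state_right)
  if (taxon_profile == "polydesmidan" &&
      any(states %in% c("ANTERIOR_GONOPOD", "POSTERIOR_GONOPOD")))
    stop("ANTERIOR/POSTERIOR gonopod states require the julidan profile",
         call. = FALSE)
  if (taxon_profile == "julidan" && any(states == "GONOPOD_GENERIC"))
    stop("GONOPOD_GENERIC requires the polydesmidan profile", call. = FALSE)
  if (is.null(ring_map)) ring_map <- build_ring_map(L)
  stopifnot(inherits(ring_map, "ring_map"))
  if (ring_map$L != L)
    stop(sprintf("ring map covers %d leg pairs but phenotype has %d",
                 ring_map$L, L), call. = FALSE)
  structure(list(units = units, taxon_profile = taxon_profile,
                 ring_map = ring_map, provenance = provenance,
                 stadium = as.integer(stadium),
                 podous_rings = as.integer(podous_rings)),
            class = "phenotype")
}

#' @export
print.phenotype <- function(x, ...) {
  cat(sprintf("Phenotype (%s profile): %d leg pairs, %d physical rings\n",
              x$taxon_profile, nrow(x$units),
              max(x$ring_map$table$physical_index)))
  if (nzchar(x$provenance)) cat(" ", x$provenance, "\n")
  g <- gonopod_positions(x)
  if (length(g)) {
    cat("  gonopod-bearing leg pairs:", paste(g, collapse = ", "), "\n")
    rings <- sort(unique(vapply(g, function(j)
      leg_pair_to_ring(j, x$ring_map)[["comparative"]], integer(1))))
    cat("  gonopod-bearing comparative rings:",
        paste(rings, collapse = ", "), "\n")
  } else cat("  no gonopods\n")
  if (length(x$ring_map$fusions))
    cat("  ring fusions:",
        paste(vapply(x$ring_map$fusions, paste, character(1),
                     collapse = "+"), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.phenotype <- function(object, ...) {
  u <- object$units
  tab <- table(factor(c(u$state_left, u$state_right),
                      levels = APPENDAGE_STATES))
  asym <- sum(u$state_left != u$state_right)
  out <- list(taxon_profile = object$taxon_profile, L = nrow(u),
              state_counts = tab, n_asymmetric = asym,
              gonopod_positions = gonopod_positions(object),
              runs = decompose_runs(gonopod_positions(object)))
  class(out) <- "summary.phenotype"
  out
}

#' @export
print.summary.phenotype <- function(x, ...) {
  cat(sprintf("Phenotype summary (%s), %d leg pairs, %d asymmetric position(s)\n",
              x$taxon_profile, x$L, x$n_asymmetric))
  print(x$state_counts)
  if (length(x$gonopod_positions)) {
    cat("gonopod positions:", paste(x$gonopod_positions, collapse = ", "),
        "\n")
    print(x$runs)
  }
  invisible(x)
}

#' @export
as.data.frame.phenotype <- function(x, ...) x$units

#' @export
plot.phenotype <- function(x, ...) {
  u <- x$units
  L <- nrow(u)
  cols <- c(WALKING_LEG = "grey80", ANTERIOR_GONOPOD = "firebrick",
            POSTERIOR_GONOPOD = "darkorange", GONOPOD_GENERIC = "firebrick",
            ATROPHIED_LEG = "steelblue", ABSENT = "white")
  graphics::plot(NULL, xlim = c(0.5, L + 0.5), ylim = c(0.25, 2.75),
                 xlab = "leg pair (collum excluded)", ylab = "", yaxt = "n",
                 main = "Appendage states along the trunk", ...)
  graphics::axis(2, at = c(1, 2), labels = c("right", "left"), las = 1)
  graphics::rect(u$leg_pair - 0.45, 1.6, u$leg_pair + 0.45, 2.4,
                 col = cols[u$state_left], border = "grey40")
  graphics::rect(u$leg_pair - 0.45, 0.6, u$leg_pair + 0.45, 1.4,
                 col = cols[u$state_right], border = "grey40")
  invisible(x)
}

# ---- TSV round-trip ---------------------------------------------------------

#' Read / write a phenotype as TSV
#'
#' The format is a tab-separated table with header
#' `position  side  state  annotation`, where `side` is `L`, `R`, or `B`
#' (both sides identical), preceded by `#`-prefixed metadata lines
#' (`# taxon_profile:`, `# provenance:`, `# stadium:`, `# podous_rings:`,
#' `# fusion: a,b` once per ring fusion). Empty annotations are written as
#' `.`. The round trip `read_phenotype(write_phenotype(ph))` is the
#' identity.
#'
#' Rows with side `L` only leave the right side `ABSENT` (and vice versa),
#' which covers unilateral teratologies. Duplicate `(position, side)` rows,
#' gaps in the position sequence, and unknown states are parse errors that
#' report the offending line number.
#'
#' @param path File path.
#' @param ph A [phenotype()] object.
#' @return `read_phenotype` returns a validated [phenotype()];
#'   `write_phenotype` invisibly returns `path`.
#' @export
read_phenotype <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty phenotype file", call. = FALSE)
  meta_idx <- grep("^#", lines)
  meta <- lines[meta_idx]
  get_meta <- function(key) {
    m <- grep(sprintf("^#\\s*%s:", key), meta, value = TRUE)
    if (!length(m)) return(NULL)
    trimws(sub(sprintf("^#\\s*%s:", key), "", m[1]))
  }
  taxon <- get_meta("taxon_profile") %||% "julidan"
  provenance <- get_meta("provenance") %||% ""
  stadium <- as.integer(get_meta("stadium") %||% NA)
  podous <- as.integer(get_meta("podous_rings") %||% NA)
  fus_lines <- grep("^#\\s*fusion:", meta, value = TRUE)
  fusions <- lapply(fus_lines, function(l)
    as.integer(strsplit(trimws(sub("^#\\s*fusion:", "", l)), ",")[[1]]))

  body_idx <- setdiff(seq_along(lines), meta_idx)
  body_idx <- body_idx[nzchar(trimws(lines[body_idx]))]
  if (!length(body_idx)) stop("phenotype file has no data rows", call. = FALSE)
  header <- strsplit(lines[body_idx[1]], "\t")[[1]]
  req <- c("position", "side", "state")
  if (!all(req %in% header))
    stop("phenotype TSV header must contain: position, side, state",
         call. = FALSE)
  rows_idx <- body_idx[-1]
  if (!length(rows_idx)) stop("phenotype file has no data rows", call. = FALSE)

  L <- 0L
  recs <- vector("list", length(rows_idx))
  for (i in seq_along(rows_idx)) {
    ln <- rows_idx[i]
    f <- strsplit(lines[ln], "\t")[[1]]
    if (length(f) < length(req))
      stop(sprintf("line %d: expected at least %d tab-separated fields",
                   ln, length(req)), call. = FALSE)
    rec <- stats::setNames(as.list(f), header[seq_along(f)])
    pos <- suppressWarnings(as.integer(rec$position))
    if (is.na(pos) || pos < 1L)
      stop(sprintf("line %d: invalid position '%s'", ln, rec$position),
           call. = FALSE)
    if (!rec$side %in% c("L", "R", "B"))
      stop(sprintf("line %d: side must be L, R or B; got '%s'", ln, rec$side),
           call. = FALSE)
    if (!rec$state %in% APPENDAGE_STATES)
      stop(sprintf("line %d: unknown appendage state '%s'", ln, rec$state),
           call. = FALSE)
    ann <- rec$annotation %||% "."
    recs[[i]] <- list(line = ln, pos = pos, side = rec$side,
                      state = rec$state,
                      annotation = if (identical(ann, ".")) "" else ann)
    L <- max(L, pos)
  }

  sl <- rep(NA_character_, L); sr <- rep(NA_character_, L)
  ann <- rep("", L)
  for (r in recs) {
    sides <- if (r$side == "B") c("L", "R") else r$side
    for (s in sides) {
      v <- if (s == "L") sl else sr
      if (!is.na(v[r$pos]))
        stop(sprintf("line %d: duplicate state for position %d side %s",
                     r$line, r$pos, s), call. = FALSE)
      if (s == "L") sl[r$pos] <- r$state else sr[r$pos] <- r$state
    }
    if (nzchar(r$annotation)) ann[r$pos] <- r$annotation
  }
  covered <- !(is.na(sl) & is.na(sr))
  if (!all(covered))
    stop("gap in position sequence: no row for position(s) ",
         paste(which(!covered), collapse = ", "), call. = FALSE)
  sl[is.na(sl)] <- "ABSENT"
  sr[is.na(sr)] <- "ABSENT"

  units <- data.frame(leg_pair = seq_len(L), state_left = sl,
                      state_right = sr, annotation = ann,
                      stringsAsFactors = FALSE)
  phenotype(units, taxon_profile = taxon,
            ring_map = build_ring_map(L, fusions = fusions),
            provenance = provenance, stadium = stadium,
            podous_rings = podous)
}

#' @rdname read_phenotype
#' @export
write_phenotype <- function(ph, path) {
  stopifnot(inherits(ph, "phenotype"))
  meta <- c(sprintf("# taxon_profile: %s", ph$taxon_profile))
  if (nzchar(ph$provenance))
    meta <- c(meta, sprintf("# provenance: %s", ph$provenance))
  if (!is.na(ph$stadium))
    meta <- c(meta, sprintf("# stadium: %d", ph$stadium))
  if (!is.na(ph$podous_rings))
    meta <- c(meta, sprintf("# podous_rings: %d", ph$podous_rings))
  for (f in ph$ring_map$fusions)
    meta <- c(meta, sprintf("# fusion: %d,%d", f[1], f[2]))
  u <- ph$units
  rows <- character(0)
  for (i in seq_len(nrow(u))) {
    a <- if (nzchar(u$annotation[i])) u$annotation[i] else "."
    if (u$state_left[i] == u$state_right[i]) {
      rows <- c(rows, paste(u$leg_pair[i], "B", u$state_left[i], a,
                            sep = "\t"))
    } else {
      keep_l <- u$state_left[i] != "ABSENT"
      keep_r <- u$state_right[i] != "ABSENT"
      if (keep_l)
        rows <- c(rows, paste(u$leg_pair[i], "L", u$state_left[i], a,
                              sep = "\t"))
      if (keep_r)
        rows <- c(rows, paste(u$leg_pair[i], "R", u$state_right[i], a,
                              sep = "\t"))
    }
  }
  writeLines(c(meta, paste("position", "side", "state", "annotation",
                           sep = "\t"), rows), path)
  invisible(path)
}
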