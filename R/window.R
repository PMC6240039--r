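# window half-width in cells for a square window of full side d metres:
# members are the cells whose centres fall inside the square, i.e. offsets
# with |dx| * res <= d/2  ->  radius floor(d / (2 res))
window_radius <- function(d, resolution) {
  if (d < resolution) {
    abort(sprintf("window size d = %g m is smaller than the resolution (%g m)",
                  d, resolution))
  }
  as.integer(floor(d / (2 * resolution)))
}

#' Extract the square window around a cell
#'
#' Members are all valid cells whose centres fall in the axis-aligned square
#' of side `d` centred on the centre cell; the window is clipped at the map
#' boundary (`truncated = TRUE` when that happens).
#'
#' @param pair A [change_pair()].
#' @param center Integer length-2 vector `c(row, col)` of the centre cell.
#' @param d Window side length in metres (`d >= resolution`).
#' @return An object of class `dixon_window`: centre, requested and effective
#'   `d`, the bounding rows/cols, a two-column matrix of member cell indices
#'   and the truncation flag.
#' @export
extract_window <- function(pair, center, d) {
  stopifnot(inherits(pair, "change_pair"))
  center <- as.integer(center)
  nr <- nrow(pair$t1); nc <- ncol(pair$t1)
  if (center[1] < 1 || center[1] > nr || center[2] < 1 || center[2] > nc) {
    abort("window centre outside the grid")
  }
  if (is.na(pair$t1[center[1], center[2]])) {
    abort("window centre falls on a nodata cell")
  }
  k <- window_radius(d, pair$resolution)
  new_window(pair, center, requested_d = d, radius = k, extra_rings = 0L)
}

new_window <- function(pair, center, requested_d, radius, extra_rings) {
  nr <- nrow(pair$t1); nc <- ncol(pair$t1)
  r1 <- max(1L, center[1] - radius); r2 <- min(nr, center[1] + radius)
  c1 <- max(1L, center[2] - radius); c2 <- min(nc, center[2] + radius)
  truncated <- (r2 - r1 < 2L * radius) || (c2 - c1 < 2L * radius)
  sub <- pair$t1[r1:r2, c1:c2, drop = FALSE]
  idx <- which(!is.na(sub), arr.ind = TRUE)
  members <- cbind(row = idx[, 1] + r1 - 1L, col = idx[, 2] + c1 - 1L)
  structure(
    list(center = center, requested_d = requested_d,
         effective_d = requested_d + 2 * pair$resolution * extra_rings,
         radius = radius, rows = c(r1, r2), cols = c(c1, c2),
         members = members, truncated = truncated),
    class = "dixon_window"
  )
}

#' @export
print.dixon_window <- function(x, ...) {
  cat(sprintf(
    "<dixon_window> centre (%d, %d), d = %g m (effective %g m), %d members%s\n",
    x$center[1], x$center[2], x$requested_d, x$effective_d,
    nrow(x$members), if (x$truncated) ", truncated at map boundary" else ""))
  invisible(x)
}

#' Space-time 2x2 contingency table for a window
#'
#' Counts, over the member cells of the window, persistence of the target
#' class (`Naa`: target at both dates), loss (`Nab`: target then other), gain
#' (`Nba`: other then target) and persistence of the other class (`Nbb`). The
#' label totals are taken over *both* dates: `Na = 2 Naa + Nab + Nba`,
#' `Nb = 2 Nbb + Nab + Nba`, `N = Na + Nb = 2 m`. Single-date (row) totals
#' are kept alongside for reporting.
#'
#' @param window A [extract_window()] result.
#' @param pair The [change_pair()] the window was extracted from.
#' @return A `contingency_table` object; see [as_contingency_table()] for the
#'   fields.
#' @export
contingency_table <- function(window, pair) {
  stopifnot(inherits(window, "dixon_window"), inherits(pair, "change_pair"))
  if (nrow(window$members) == 0) abort("empty window")
  v1 <- pair$t1[window$members]
  v2 <- pair$t2[window$members]
  as_contingency_table(
    naa = sum(v1 == 1 & v2 == 1), nab = sum(v1 == 1 & v2 == 0),
    nba = sum(v1 == 0 & v2 == 1), nbb = sum(v1 == 0 & v2 == 0)
  )
}

#' Build a contingency table from its four counts
#'
#' @param naa,nab,nba,nbb Cell counts: target-target, target-other,
#'   other-target, other-other across the two dates.
#' @return An object of class `contingency_table` with fields `Naa`, `Nab`,
#'   `Nba`, `Nbb`, `m` (cells), both-date totals `Na`, `Nb`, `N = 2 m`, and
#'   single-date totals `Na_t1`, `Na_t2`.
#' @examples
#' as_contingency_table(4, 6, 1, 7)
#' @export
as_contingency_table <- function(naa, nab, nba, nbb) {
  counts <- c(naa, nab, nba, nbb)
  if (any(counts < 0) || any(counts %% 1 != 0)) {
    abort("contingency counts must be non-negative integers")
  }
  naa <- as.integer(naa); nab <- as.integer(nab)
  nba <- as.integer(nba); nbb <- as.integer(nbb)
  m <- naa + nab + nba + nbb
  structure(
    list(Naa = naa, Nab = nab, Nba = nba, Nbb = nbb, m = m,
         Na = 2 * naa + nab + nba, Nb = 2 * nbb + nab + nba, N = 2 * m,
         Na_t1 = naa + nab, Na_t2 = naa + nba),
    class = "contingency_table"
  )
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> m = %d cells (N = %d space-time labels)\n",
              x$m, x$N))
  m <- rbind(c(x$Naa, x$Nab), c(x$Nba, x$Nbb))
  dimnames(m) <- list(c("t1 target", "t1 other"), c("t2 target", "t2 other"))
  print(m)
  cat(sprintf("  both-date totals: Na = %d, Nb = %d\n", x$Na, x$Nb))
  invisible(x)
}

#' Edge correction by local window enlargement
#'
#' Enlarges the window one cell ring at a time until both `Naa` and `Nab`
#' exceed `min_count`, or until the window covers the whole map. Windows for
#' which the condition is unreachable (e.g. a map with no loss anywhere) are
#' returned with `flagged = TRUE` and are labelled `undefined` downstream --
#' this is a flagged outcome, not an error.
#'
#' @param window A [extract_window()] result.
#' @param pair The [change_pair()].
#' @param min_count Both `Naa` and `Nab` must be strictly greater than this
#'   (default 4) for the segregation index to be well defined and stable.
#' @return A list with elements `window` (possibly enlarged), `table` (its
#'   [contingency_table()]) and `flagged`.
#' @export
edge_correct <- function(window, pair, min_count = 4) {
  stopifnot(inherits(window, "dixon_window"))
  nr <- nrow(pair$t1); nc <- ncol(pair$t1)
  w <- window
  rings <- 0L
  repeat {
    tab <- contingency_table(w, pair)
    if (tab$Naa > min_count && tab$Nab > min_count) {
      return(list(window = w, table = tab, flagged = FALSE))
    }
    covers_map <- w$rows[1] == 1L && w$cols[1] == 1L &&
      w$rows[2] == nr && w$cols[2] == nc
    if (covers_map) {
      return(list(window = w, table = tab, flagged = TRUE))
    }
    rings <- rings + 1L
    w <- new_window(pair, window$center, window$requested_d,
                    radius = window$radius + rings, extra_rings = rings)
  }
}
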