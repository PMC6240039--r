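#' Land-cover transition matrix with net-change accounting
#'
#' Cross-tabulates the class labels of two aligned grids (rows = classes at
#' the first date, columns = classes at the second date) and reports, per
#' class, the net change computed as column gains minus row losses:
#' `net[c] = (colsum(c) - diagonal) - (rowsum(c) - diagonal)`. Counts are
#' given in cells and as percent of the total valid area; net change is
#' reported in both units.
#'
#' @param g1,g2 Aligned [landcover_grid()] objects of identical shape and
#'   resolution (use [align_pair()] first if needed).
#' @return An object of class `transition_matrix` with elements `counts`,
#'   `percent`, `net_cells`, `net_percent`, `resolution`.
#' @examples
#' g1 <- landcover_grid(matrix(c(1, 1, 2, 2), 2), 50)
#' g2 <- landcover_grid(matrix(c(1, 2, 2, 2), 2), 50)
#' transition_matrix(g1, g2)
#' @export
transition_matrix <- function(g1, g2) {
  stopifnot(inherits(g1, "landcover_grid"), inherits(g2, "landcover_grid"))
  if (!identical(dim(g1$values), dim(g2$values)) ||
      abs(g1$resolution - g2$resolution) > 1e-9) {
    abort("grids are not aligned; call align_pair() first")
  }
  ok <- !is.na(g1$values) & !is.na(g2$values)
  if (!any(ok)) abort("no valid overlapping cells")
  cn <- g1$class_names %||% g2$class_names
  labs <- as.character(sort(unique(c(g1$values[ok], g2$values[ok]))))
  lvls <- if (!is.null(cn)) union(names(cn), labs) else labs
  f1 <- factor(as.character(g1$values[ok]), levels = lvls)
  f2 <- factor(as.character(g2$values[ok]), levels = lvls)
  counts <- unclass(table(f1, f2))
  names(dimnames(counts)) <- NULL
  if (!is.null(cn)) {
    shown <- ifelse(lvls %in% names(cn), cn[lvls], lvls)
    dimnames(counts) <- list(shown, shown)
  }
  percent <- counts / sum(counts) * 100
  structure(
    list(counts = counts, percent = percent,
         net_cells = net_change(counts), net_percent = net_change(percent),
         resolution = g1$resolution),
    class = "transition_matrix"
  )
}

#' Net class change from a square transition matrix
#'
#' For each class, gains are the off-diagonal column sum (area entering the
#' class) and losses the off-diagonal row sum (area leaving it); the net is
#' gains minus losses, in whatever units the matrix is expressed in (cells,
#' hectares or percent of area). The nets of a matrix in cells always sum
#' to zero.
#'
#' @param mat Square numeric matrix, rows = first date, columns = second date.
#' @return Named numeric vector of per-class net change.
#' @examples
#' m <- rbind(c(38, 10, 0, 8, 0), c(5, 26, 0, 7, 0), c(4, 2, 2, 10, 0),
#'            c(1, 2, 0, 32, 0), c(0, 0, 0, 0, 2))
#' net_change(m)[1] # gains (5 + 4 + 1) minus losses (10 + 8) = -8
#' @export
net_change <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) abort("transition matrix must be square")
  d <- diag(mat)
  (colSums(mat) - d) - (rowSums(mat) - d)
}

#' @export
print.transition_matrix <- function(x, digits = 1, ...) {
  cat("<transition_matrix> rows = first date, columns = second date\n")
  cat("\nCells:\n")
  print(cbind(x$counts, net = x$net_cells))
  cat("\nPercent of valid area:\n")
  print(round(cbind(x$percent, net = x$net_percent), digits))
  invisible(x)
}

#' Long tibble view of a transition matrix
#'
#' @param x A [transition_matrix()].
#' @param ... Unused.
#' @return Tibble with columns `from`, `to`, `cells`, `percent`.
#' @export
tidy.transition_matrix <- function(x, ...) {
  cls <- rownames(x$counts)
  tibble::tibble(
    from = rep(cls, times = ncol(x$counts)),
    to = rep(cls, each = nrow(x$counts)),
    cells = as.vector(x$counts),
    percent = as.vector(x$percent)
  )
}

#' @export
glance.transition_matrix <- function(x, ...) {
  tibble::tibble(
    n_cells = sum(x$counts),
    n_classes = nrow(x$counts),
    cells_changed = sum(x$counts) - sum(diag(x$counts)),
    percent_changed = 100 - sum(diag(x$percent)),
    area_ha = sum(x$counts) * x$resolution^2 / 1e4
  )
}

#' Write a transition matrix as delimited tables
#'
#' @param x A [transition_matrix()].
#' @param path Output TSV path; percent and net columns are joined in long
#'   format via [tidy.transition_matrix()].
#' @return `path`, invisibly.
#' @export
write_transition <- function(x, path) {
  readr::write_tsv(tidy(x), path)
  invisible(path)
}
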