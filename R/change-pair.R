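#' Binarize a land-cover grid against a target class
#'
#' Returns a 0/1 matrix with 1 where the cell label equals the target class
#' and 0 for every other label; nodata cells stay `NA`. The target may be
#' given as a class name (matched exactly against `class_names` after
#' whitespace trimming) or as a raw label.
#'
#' @param grid A [landcover_grid()].
#' @param target_class Class name or label identifying the target class.
#' @return Integer 0/1 matrix with `NA` at nodata cells.
#' @examples
#' g <- landcover_grid(matrix(c(1, 2, 3, 1), 2), 50,
#'                     class_names = c("1" = "cork", "2" = "agri", "3" = "pasture"))
#' binarize(g, "cork")
#' @export
binarize <- function(grid, target_class) {
  stopifnot(inherits(grid, "landcover_grid"))
  target <- trimws(as.character(target_class))
  label <- target
  if (!is.null(grid$class_names) && target %in% grid$class_names) {
    label <- names(grid$class_names)[match(target, grid$class_names)]
  }
  v <- grid$values
  out <- matrix(NA_integer_, nrow(v), ncol(v))
  ok <- !is.na(v)
  out[ok] <- as.integer(as.character(v[ok]) == label)
  if (sum(out[ok]) == 0) {
    warn(paste0("target class '", target, "' is absent: binary layer is all zero"))
  }
  out
}

#' Aligned two-date binary change pair
#'
#' The central input container of the analysis: two 0/1 grids of identical
#' shape (target class vs everything else at dates t1 and t2) on a shared
#' valid-cell mask. Build one from classified grids with [change_pair()] or
#' directly from 0/1 matrices with [as_change_pair()] (synthetic data, tests).
#'
#' @param g1,g2 [landcover_grid()] objects for the two dates; they are aligned
#'   with [align_pair()] first.
#' @param target_class Target class name or label, passed to [binarize()].
#' @return An object of class `change_pair` with elements `t1`, `t2`
#'   (0/1 matrices, `NA` = invalid), `resolution`, `origin`, `target_class`.
#' @export
change_pair <- function(g1, g2, target_class) {
  al <- align_pair(g1, g2)
  as_change_pair(binarize(al$g1, target_class), binarize(al$g2, target_class),
                 resolution = al$g1$resolution, origin = al$g1$origin,
                 target_class = trimws(as.character(target_class)))
}

#' @rdname change_pair
#' @param t1,t2 0/1 matrices of identical shape (`NA` = invalid cell).
#' @param resolution Cell size in metres.
#' @param origin Lower-left corner map coordinates.
#' @export
as_change_pair <- function(t1, t2, resolution = 50, origin = c(0, 0),
                           target_class = "target") {
  if (!identical(dim(t1), dim(t2))) abort("t1 and t2 must have identical shape")
  storage.mode(t1) <- "integer"; storage.mode(t2) <- "integer"
  mask <- is.na(t1) | is.na(t2)
  t1[mask] <- NA_integer_; t2[mask] <- NA_integer_
  ok <- !mask
  if (!all(t1[ok] %in% 0:1) || !all(t2[ok] %in% 0:1)) {
    abort("values must be 0/1 on valid cells")
  }
  structure(
    list(t1 = t1, t2 = t2, resolution = as.numeric(resolution),
         origin = as.numeric(origin), target_class = target_class),
    class = "change_pair"
  )
}

#' @export
print.change_pair <- function(x, ...) {
  ok <- !is.na(x$t1)
  cat(sprintf("<change_pair> '%s' vs other, %d x %d cells at %g m (%d valid)\n",
              x$target_class, nrow(x$t1), ncol(x$t1), x$resolution, sum(ok)))
  cat(sprintf("  target fraction: %.3f (t1), %.3f (t2); %d loss / %d gain cells\n",
              mean(x$t1[ok]), mean(x$t2[ok]),
              sum(x$t1[ok] == 1 & x$t2[ok] == 0),
              sum(x$t1[ok] == 0 & x$t2[ok] == 1)))
  invisible(x)
}

#' @export
dim.change_pair <- function(x) dim(x$t1)

#' Per-cell tibble view of a change pair
#'
#' @param x A `change_pair`.
#' @param ... Unused.
#' @return A tibble with one row per valid cell: `row`, `col`, `x`, `y`,
#'   `t1`, `t2`.
#' @export
tidy.change_pair <- function(x, ...) {
  idx <- which(!is.na(x$t1), arr.ind = TRUE)
  xs <- x$origin[1] + (idx[, 2] - 0.5) * x$resolution
  ys <- x$origin[2] + (nrow(x$t1) - idx[, 1] + 0.5) * x$resolution
  v1 <- x$t1[idx]; v2 <- x$t2[idx]
  tibble::tibble(
    row = idx[, 1], col = idx[, 2], x = xs, y = ys, t1 = v1, t2 = v2
  ) |> dplyr::arrange(.data$row, .data$col)
}
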