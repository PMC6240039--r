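# numeric matrix of one cells-column on the map grid (NA off the mask)
layer_matrix <- function(map, column) {
  m <- matrix(NA_real_, map$dim[1], map$dim[2])
  m[cbind(map$cells$row, map$cells$col)] <- map$cells[[column]]
  m
}

label_codes <- c(random = 0, segregation = 1, association = 2, undefined = 3)

#' Write all result layers of a segregation map
#'
#' Writes georeferenced ESRI ASCII layers for the index (`saa.asc`), the C
#' p-value (`p_c.asc`), the classification (`label.asc`, coded 0 = random,
#' 1 = segregation, 2 = association, 3 = undefined) and the standardized
#' uncertainty (`uncertainty.asc`); the full per-cell table
#' (`cells.tsv`); and a run-metadata record (`run_metadata.json`) holding
#' every parameter and the seed, sufficient to reproduce the run exactly.
#'
#' @param map A [local_dixon_map()] result.
#' @param out_dir Output directory (created if needed).
#' @param transition Optional [transition_matrix()] written as
#'   `transition.tsv`.
#' @return Invisible character vector of the files written.
#' @export
write_results <- function(map, out_dir, transition = NULL) {
  stopifnot(inherits(map, "dixon_map"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) abort(paste0("directory not writable: ", out_dir))
  res <- map$resolution; org <- map$origin
  files <- character(0)
  wl <- function(mat, name, digits = 10) {
    p <- file.path(out_dir, name)
    write_landcover(mat, p, resolution = res, origin = org, digits = digits)
    p
  }
  files <- c(files, wl(layer_matrix(map, "Saa"), "saa.asc"))
  files <- c(files, wl(layer_matrix(map, "p_C"), "p_c.asc"))
  lab <- matrix(NA_real_, map$dim[1], map$dim[2])
  lab[cbind(map$cells$row, map$cells$col)] <- label_codes[map$cells$label]
  files <- c(files, wl(lab, "label.asc"))
  files <- c(files, wl(layer_matrix(map, "uncertainty"), "uncertainty.asc"))
  cells_path <- file.path(out_dir, "cells.tsv")
  readr::write_tsv(map$cells, cells_path)
  files <- c(files, cells_path)
  if (!is.null(transition)) {
    files <- c(files, write_transition(transition, file.path(out_dir, "transition.tsv")))
  }
  meta <- list(
    package = "dixonscan",
    version = as.character(utils::packageVersion("dixonscan")),
    d = map$d, nsim = map$nsim, alpha = map$alpha, seed = map$seed,
    min_count = map$min_count, resolution = res, origin = org,
    dim = map$dim, target_class = map$target_class,
    n_cells = nrow(map$cells), n_undefined = map$n_undefined,
    label_codes = as.list(label_codes)
  )
  meta_path <- file.path(out_dir, "run_metadata.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(files, meta_path))
}

#' Write a change pair as two ASCII rasters
#'
#' @param pair A [change_pair()].
#' @param out_dir Output directory; `t1.asc` and `t2.asc` are written so the
#'   pair can be fed back through [load_landcover()].
#' @return Invisible character vector of the two paths.
#' @export
write_change_pair <- function(pair, out_dir) {
  stopifnot(inherits(pair, "change_pair"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(out_dir, "t1.asc"); p2 <- file.path(out_dir, "t2.asc")
  write_landcover(pair$t1, p1, resolution = pair$resolution, origin = pair$origin)
  write_landcover(pair$t2, p2, resolution = pair$resolution, origin = pair$origin)
  invisible(c(p1, p2))
}
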