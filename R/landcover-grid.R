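#' Regular-grid categorical land-cover map
#'
#' `landcover_grid()` wraps a matrix of integer class labels together with its
#' georeferencing (cell size and lower-left corner) and an optional mapping
#' from labels to class names. Nodata cells are stored as `NA`. Row 1 of the
#' matrix is the *top* (northernmost) row of the map; coordinates are
#' cell-centred.
#'
#' @param values Integer matrix of class labels; `NA` marks nodata cells.
#' @param resolution Cell size in metres (single positive number).
#' @param origin Numeric length-2 vector, map coordinates `c(x, y)` of the
#'   lower-left corner of the grid.
#' @param class_names Optional named character vector mapping label (name,
#'   as character) to class name, e.g. `c("1" = "cork oak forest")`.
#'
#' @return An object of class `landcover_grid`.
#' @examples
#' g <- landcover_grid(matrix(c(1, 2, 2, 1), 2), resolution = 50)
#' g
#' @export
landcover_grid <- function(values, resolution, origin = c(0, 0),
                           class_names = NULL) {
  if (!is.matrix(values)) abort("`values` must be a matrix.")
  storage.mode(values) <- "integer"
  if (!is.numeric(resolution) || length(resolution) != 1 || resolution <= 0) {
    abort("`resolution` must be a single positive number (metres).")
  }
  if (length(origin) != 2 || !is.numeric(origin)) {
    abort("`origin` must be c(x, y).")
  }
  if (!is.null(class_names)) {
    class_names <- setNames(trimws(as.character(class_names)),
                            trimws(names(class_names)))
    labs <- unique(values[!is.na(values)])
    missing <- setdiff(as.character(labs), names(class_names))
    if (length(missing) > 0) {
      abort(paste0("labels without an entry in `class_names`: ",
                   paste(missing, collapse = ", ")))
    }
  }
  structure(
    list(values = values, resolution = as.numeric(resolution),
         origin = as.numeric(origin), class_names = class_names),
    class = "landcover_grid"
  )
}

#' @export
print.landcover_grid <- function(x, ...) {
  nv <- sum(!is.na(x$values))
  cat(sprintf("<landcover_grid> %d x %d cells at %g m (%d valid)\n",
              nrow(x$values), ncol(x$values), x$resolution, nv))
  cat(sprintf("  origin (lower-left): %g, %g\n", x$origin[1], x$origin[2]))
  labs <- sort(unique(x$values[!is.na(x$values)]))
  shown <- vapply(as.character(labs), function(l) {
    if (!is.null(x$class_names) && l %in% names(x$class_names))
      paste0(l, "=", x$class_names[[l]]) else l
  }, character(1))
  cat("  classes:", paste(shown, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.landcover_grid <- function(x) dim(x$values)

# map x/y of cell centres; row 1 is the top row
grid_x <- function(grid, col) grid$origin[1] + (col - 0.5) * grid$resolution
grid_y <- function(grid, row) {
  grid$origin[2] + (nrow(grid$values) - row + 0.5) * grid$resolution
}

#' Read a categorical raster (ESRI ASCII grid)
#'
#' Reads a single-band categorical raster in ESRI ASCII grid format (the
#' plain-text `.asc` format with an `ncols/nrows/xllcorner/yllcorner/cellsize`
#' header). Values must be integers; a floating-point band with non-integer
#' values signals a mis-specified input and is an error. GeoTIFF input is not
#' supported; convert to ASCII grid first (e.g. `gdal_translate -of AAIGrid`).
#'
#' @param path Path to the `.asc` file.
#' @param class_names Optional label-to-name mapping, either a named character
#'   vector (see [landcover_grid()]) or a path to a two-column delimited text
#'   file (label, name) read with [read_class_map()].
#'
#' @return A [landcover_grid()].
#' @seealso [write_landcover()], [read_class_map()]
#' @export
load_landcover <- function(path, class_names = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    abort(paste0("GeoTIFF input is not supported: ", path,
                 "\nConvert to ESRI ASCII grid (.asc) first."))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list()
  i <- 0
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "xllcenter",
                   "yllcenter", "cellsize", "nodata_value") &&
        length(parts) == 2 && !is.na(suppressWarnings(as.numeric(parts[2])))) {
      hdr[[key]] <- as.numeric(parts[2])
      i <- i + 1
    } else {
      break
    }
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) {
    abort(paste0("not an ESRI ASCII grid (missing ",
                 paste(setdiff(need, names(hdr)), collapse = "/"),
                 " header): ", path))
  }
  body <- paste(lines[-seq_len(i)], collapse = " ")
  vals <- suppressWarnings(as.numeric(strsplit(trimws(body), "\\s+")[[1]]))
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  if (anyNA(vals) || length(vals) != nc * nr) {
    abort(paste0("could not parse ", nc * nr, " numeric cells from: ", path))
  }
  nodata <- hdr$nodata_value %||% -9999
  vals[vals == nodata] <- NA
  if (any(vals[!is.na(vals)] %% 1 != 0)) {
    abort(paste0("non-integer cell values in categorical raster: ", path))
  }
  # cell-centre registered headers shift the corner by half a cell
  corner <- function(ll, center) {
    if (!is.null(ll)) ll
    else if (!is.null(center)) center - hdr$cellsize / 2
    else 0
  }
  xll <- corner(hdr$xllcorner, hdr$xllcenter)
  yll <- corner(hdr$yllcorner, hdr$yllcenter)
  if (is.character(class_names) && is.null(names(class_names)) &&
      length(class_names) == 1 && file.exists(class_names)) {
    class_names <- read_class_map(class_names)
  }
  landcover_grid(matrix(as.integer(vals), nrow = nr, ncol = nc, byrow = TRUE),
                 resolution = hdr$cellsize, origin = c(xll, yll),
                 class_names = class_names)
}

#' Write a grid as an ESRI ASCII raster
#'
#' @param grid A [landcover_grid()] or a plain numeric matrix.
#' @param path Output `.asc` path.
#' @param resolution,origin Georeferencing, only used when `grid` is a bare
#'   matrix.
#' @param nodata Value written for `NA` cells.
#' @param digits Significant digits for non-integer layers.
#' @return `path`, invisibly.
#' @export
write_landcover <- function(grid, path, resolution = NULL, origin = c(0, 0),
                            nodata = -9999, digits = 10) {
  if (inherits(grid, "landcover_grid")) {
    m <- grid$values; resolution <- grid$resolution; origin <- grid$origin
  } else {
    m <- grid
    if (is.null(resolution)) abort("`resolution` required for a bare matrix.")
  }
  fmt <- function(v) {
    v[is.na(v)] <- nodata
    if (all(v %% 1 == 0)) format(v, scientific = FALSE, trim = TRUE)
    else formatC(v, digits = digits, format = "g")
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(m)), paste("nrows", nrow(m)),
    paste("xllcorner", format(origin[1], scientific = FALSE)),
    paste("yllcorner", format(origin[2], scientific = FALSE)),
    paste("cellsize", format(resolution, scientific = FALSE)),
    paste("NODATA_value", nodata)
  ), con)
  writeLines(apply(m, 1, function(r) paste(fmt(r), collapse = " ")), con)
  invisible(path)
}

#' Read a label-to-name class map
#'
#' Two-column delimited text table (label, name); a header line is detected and
#' skipped when the first field is not numeric.
#'
#' @param path Path to the table.
#' @return Named character vector mapping label to class name.
#' @export
read_class_map <- function(path) {
  tab <- utils::read.table(path, sep = "", header = FALSE,
                           stringsAsFactors = FALSE, col.names = c("label", "name"),
                           colClasses = "character", fill = TRUE)
  if (nrow(tab) > 0 && is.na(suppressWarnings(as.numeric(tab$label[1])))) {
    tab <- tab[-1, , drop = FALSE]
  }
  if (nrow(tab) == 0) abort(paste0("empty class map: ", path))
  setNames(trimws(tab$name), trimws(tab$label))
}

#' Crop two grids to their common extent
#'
#' Both grids must share the cell size and lie on the same lattice. The
#' returned grids cover the intersection of the two extents and carry the
#' combined nodata mask, so a cell is valid only where both inputs are valid.
#'
#' @param g1,g2 [landcover_grid()] objects.
#' @return A list with elements `g1` and `g2` (aligned grids of equal shape).
#' @export
align_pair <- function(g1, g2) {
  res <- g1$resolution
  if (abs(res - g2$resolution) > 1e-9) {
    abort(sprintf("resolutions differ: %g m vs %g m", res, g2$resolution))
  }
  off <- (g2$origin - g1$origin) / res
  if (any(abs(off - round(off)) > 1e-6)) {
    abort("grids are not on the same lattice (origins differ by a non-multiple of the cell size)")
  }
  ext <- function(g) c(xmin = g$origin[1], xmax = g$origin[1] + ncol(g$values) * res,
                       ymin = g$origin[2], ymax = g$origin[2] + nrow(g$values) * res)
  e1 <- ext(g1); e2 <- ext(g2)
  xmin <- max(e1["xmin"], e2["xmin"]); xmax <- min(e1["xmax"], e2["xmax"])
  ymin <- max(e1["ymin"], e2["ymin"]); ymax <- min(e1["ymax"], e2["ymax"])
  if (xmax - xmin < res / 2 || ymax - ymin < res / 2) {
    abort("grids have an empty intersection")
  }
  crop <- function(g) {
    c1 <- round((xmin - g$origin[1]) / res) + 1
    c2 <- round((xmax - g$origin[1]) / res)
    nr <- nrow(g$values)
    r1 <- nr - round((ymax - g$origin[2]) / res) + 1
    r2 <- nr - round((ymin - g$origin[2]) / res)
    landcover_grid(g$values[r1:r2, c1:c2, drop = FALSE], res,
                   origin = c(xmin, ymin), class_names = g$class_names)
  }
  a1 <- crop(g1); a2 <- crop(g2)
  mask <- is.na(a1$values) | is.na(a2$values)
  a1$values[mask] <- NA
  a2$values[mask] <- NA
  list(g1 = a1, g2 = a2)
}
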