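#' Configuration for synthetic two-date landscapes
#'
#' Describes a paired binary landscape generator mirroring the geometry of a
#' 50 m land-cover raster: grid shape, resolution, marginal target-class
#' probability, an optional clustered base map, deterministic target regions
#' and conversion patches.
#'
#' @param n_rows,n_cols Grid shape (default 200 x 200, the order of magnitude
#'   of a ~100 km2 study area at 50 m).
#' @param resolution Cell size in metres (default 50).
#' @param p_target Marginal probability of the target class (default 0.45,
#'   a realistic cover fraction for a forest-dominated landscape).
#' @param smoothing Box-smoothing radius in cells for the clustered base map
#'   used by [gen_patch_change_pair()] (default 4); larger values give larger
#'   coherent target blobs.
#' @param target_region Optional list of discs `list(row, col, radius)`
#'   (radius in metres) forced to target at the first date, on top of the
#'   clustered noise.
#' @param patches List of conversion patches from [sim_patch()].
#' @param seed Integer seed (required).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_rows = 200, n_cols = 200, resolution = 50,
                       p_target = 0.45, smoothing = 4,
                       target_region = list(), patches = list(), seed) {
  if (missing(seed)) abort("`seed` is required")
  if (n_rows < 1 || n_cols < 1) abort("grid must be non-empty")
  if (p_target < 0 || p_target > 1) abort("`p_target` must be in [0, 1]")
  if (resolution <= 0) abort("`resolution` must be positive")
  for (p in patches) {
    if (!inherits(p, "sim_patch")) abort("`patches` must be built with sim_patch()")
    if (p$row < 1 || p$row > n_rows || p$col < 1 || p$col > n_cols) {
      abort(sprintf("patch centre (%d, %d) is outside the %d x %d grid",
                    p$row, p$col, n_rows, n_cols))
    }
    if (p$radius < resolution) abort("patch radius must be >= the resolution")
  }
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         resolution = resolution, p_target = p_target, smoothing = smoothing,
         target_region = target_region, patches = patches,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Conversion patch for the synthetic generator
#'
#' @param row,col Centre cell of the circular patch.
#' @param radius Patch radius in metres.
#' @param conversion Per-cell conversion probability in `[0, 1]`.
#' @param direction `"loss"` flips target cells to other at the second date,
#'   `"gain"` the reverse.
#' @return An object of class `sim_patch`.
#' @export
sim_patch <- function(row, col, radius, conversion = 1,
                      direction = c("loss", "gain")) {
  direction <- match.arg(direction)
  if (conversion < 0 || conversion > 1) abort("`conversion` must be in [0, 1]")
  structure(list(row = as.integer(row), col = as.integer(col),
                 radius = radius, conversion = conversion,
                 direction = direction),
            class = "sim_patch")
}

# logical mask of cells whose centres lie within `radius` metres of the
# centre cell's centre (boundary inclusive)
disc_mask <- function(n_rows, n_cols, row, col, radius, resolution) {
  dr <- outer((seq_len(n_rows) - row)^2, (seq_len(n_cols) - col)^2, "+")
  sqrt(dr) * resolution <= radius + 1e-9
}

# box smoothing with edge renormalization (moving average over a
# (2r+1)^2 neighbourhood clipped at the border)
box_smooth <- function(x, r) {
  if (r < 1) return(x)
  S <- cum2d(x)
  Cnt <- cum2d(matrix(1, nrow(x), ncol(x)))
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    r1 <- max(1, i - r); r2 <- min(nr, i + r)
    c1 <- pmax(1, seq_len(nc) - r); c2 <- pmin(nc, seq_len(nc) + r)
    s <- S[r2 + 1, c2 + 1] - S[r1, c2 + 1] - S[r2 + 1, c1] + S[r1, c1]
    n <- Cnt[r2 + 1, c2 + 1] - Cnt[r1, c2 + 1] - Cnt[r2 + 1, c1] + Cnt[r1, c1]
    out[i, ] <- s / n
  }
  out
}

#' Random-labelling null pair
#'
#' Draws every space-time label independently with probability `p_target`,
#' i.e. no dependence between dates or between neighbours beyond chance --
#' the null model of the segregation test. Patches must not be configured.
#'
#' @param config A [sim_config()] without patches.
#' @return A [change_pair()].
#' @export
gen_null_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$patches) > 0) {
    abort("gen_null_pair() requires a configuration without patches")
  }
  set.seed(config$seed)
  n <- config$n_rows * config$n_cols
  t1 <- matrix(rbinom(n, 1, config$p_target), config$n_rows, config$n_cols)
  t2 <- matrix(rbinom(n, 1, config$p_target), config$n_rows, config$n_cols)
  as_change_pair(t1, t2, resolution = config$resolution,
                 target_class = "target")
}

#' Clustered pair with conversion patches
#'
#' The first date is a clustered target map: a box-smoothed Gaussian noise
#' field thresholded so that the target fraction equals `p_target` (smoothing
#' keeps windows mixed, which the edge-correction condition needs), with any
#' `target_region` discs forced to target on top. The second date copies the
#' first; inside each loss patch, target cells flip to other with the stated
#' conversion probability (gain patches flip other cells to target). Outside
#' the patches labels persist, so a configuration without patches returns two
#' identical maps.
#'
#' @param config A [sim_config()].
#' @return A [change_pair()].
#' @export
gen_patch_change_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nr <- config$n_rows; nc <- config$n_cols
  field <- box_smooth(matrix(rnorm(nr * nc), nr, nc), config$smoothing)
  t1 <- if (config$p_target <= 0) {
    matrix(0L, nr, nc)
  } else if (config$p_target >= 1) {
    matrix(1L, nr, nc)
  } else {
    matrix(as.integer(field >= quantile(field, 1 - config$p_target)), nr, nc)
  }
  for (reg in config$target_region) {
    t1[disc_mask(nr, nc, reg$row, reg$col, reg$radius, config$resolution)] <- 1L
  }
  t2 <- t1
  for (p in config$patches) {
    in_disc <- disc_mask(nr, nc, p$row, p$col, p$radius, config$resolution)
    from <- if (p$direction == "loss") 1L else 0L
    eligible <- which(in_disc & t1 == from)
    if (length(eligible) > 0) {
      flip <- runif(length(eligible)) <= p$conversion
      t2[eligible[flip]] <- 1L - from
    }
  }
  as_change_pair(t1, t2, resolution = config$resolution,
                 target_class = "target")
}
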