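# padded 2-D cumulative sum: S[i+1, j+1] = sum(x[1:i, 1:j]), NA -> 0
cum2d <- function(x) {
  x[is.na(x)] <- 0
  cs <- apply(x, 2, cumsum)
  cs <- t(apply(cs, 1, cumsum))
  rbind(0, cbind(0, cs))
}

# integral images of the four space-time states over valid cells
pair_counts <- function(pair) {
  ok <- !is.na(pair$t1) & !is.na(pair$t2)
  a <- pair$t1 == 1 & pair$t2 == 1
  b <- pair$t1 == 1 & pair$t2 == 0
  c_ <- pair$t1 == 0 & pair$t2 == 1
  d <- pair$t1 == 0 & pair$t2 == 0
  z <- function(m) { m[!ok] <- FALSE; cum2d(m) }
  list(S11 = z(a), S10 = z(b), S01 = z(c_), S00 = z(d),
       nr = nrow(pair$t1), nc = ncol(pair$t1))
}

rect_sum <- function(S, r1, r2, c1, c2) {
  S[r2 + 1, c2 + 1] - S[r1, c2 + 1] - S[r2 + 1, c1] + S[r1, c1]
}

# window counts with ring-by-ring edge enlargement; mirrors edge_correct()
scan_cell_counts <- function(ci, i, j, radius, min_count) {
  k <- radius
  repeat {
    r1 <- max(1L, i - k); r2 <- min(ci$nr, i + k)
    c1 <- max(1L, j - k); c2 <- min(ci$nc, j + k)
    naa <- rect_sum(ci$S11, r1, r2, c1, c2)
    nab <- rect_sum(ci$S10, r1, r2, c1, c2)
    nba <- rect_sum(ci$S01, r1, r2, c1, c2)
    nbb <- rect_sum(ci$S00, r1, r2, c1, c2)
    met <- naa > min_count && nab > min_count
    covers <- r1 == 1L && c1 == 1L && r2 == ci$nr && c2 == ci$nc
    if (met || covers) {
      return(list(naa = naa, nab = nab, nba = nba, nbb = nbb,
                  rings = k - radius, flagged = !met,
                  truncated = (r2 - r1 < 2L * k) || (c2 - c1 < 2L * k)))
    }
    k <- k + 1L
  }
}

# lean numeric core shared with null_ensemble(): same draws, same arithmetic
null_sims <- function(tab, nsim, seed, pmf = NULL) {
  set.seed(seed)
  m <- tab$m; Na <- tab$Na; Nb <- tab$Nb
  degenerate <- Na < 2 || Nb < 2 || m < 2
  sims <- sample_null_tables(m, Na, nsim, pmf = pmf)
  mu <- mean(sims$Naa)
  v <- var(sims$Naa)
  if (!degenerate && (!is.finite(v) || v == 0)) degenerate <- TRUE
  r <- if (degenerate) NA_real_ else cor(sims$Naa, sims$Nbb)
  sd_naa <- sqrt(v)
  z_aa <- if (degenerate) rep(NA_real_, nsim) else (sims$Naa - mu) / sd_naa
  z_bb <- if (degenerate) rep(NA_real_, nsim) else
    (sims$Nbb - (mu + m - Na)) / sd_naa
  list(sims = sims,
       Saa = log(sims$Naa / sims$Nab) - log((Na - 1) / Nb),
       z_aa = z_aa, z_bb = z_bb, C = c_statistic(z_aa, z_bb, r),
       moments = list(E_Naa = mu, Var_Naa = v, E_Nbb = mu + m - Na,
                      Var_Nbb = v, r = r),
       degenerate = degenerate)
}

# all per-cell statistics for one contingency table
cell_stats <- function(tab, nsim, seed, alpha, pmf = NULL) {
  ns <- null_sims(tab, nsim, seed, pmf = pmf)
  mo <- ns$moments
  if (ns$degenerate) {
    return(list(Saa = NA_real_, z_aa = NA_real_, z_bb = NA_real_,
                r = NA_real_, C = NA_real_, p_C = NA_real_,
                p_zaa = NA_real_, p_zbb = NA_real_, width = NA_real_,
                label = "undefined"))
  }
  sd_naa <- sqrt(mo$Var_Naa)
  z_aa <- (tab$Naa - mo$E_Naa) / sd_naa
  z_bb <- (tab$Nbb - mo$E_Nbb) / sd_naa
  C_obs <- c_statistic(z_aa, z_bb, mo$r)
  s_obs <- saa(tab)
  p_C <- mc_pvalue(C_obs, ns$C)
  p_zaa <- mc_pvalue(abs(z_aa), abs(ns$z_aa))
  p_zbb <- mc_pvalue(abs(z_bb), abs(ns$z_bb))
  s_fin <- ns$Saa[is.finite(ns$Saa)]
  width <- if (length(s_fin) >= 2) {
    unname(diff(quantile(s_fin, c(0.025, 0.975))))
  } else NA_real_
  list(Saa = s_obs, z_aa = z_aa, z_bb = z_bb, r = mo$r, C = C_obs,
       p_C = p_C, p_zaa = p_zaa, p_zbb = p_zbb, width = width,
       label = classify_cell(s_obs, p_C, alpha))
}

#' Local Dixon segregation map
#'
#' Applies the full local machinery at every valid cell of the pair: square
#' window of side `d`, edge correction by ring enlargement, space-time
#' contingency table, segregation index `Saa`, Monte Carlo null ensemble
#' under random labelling, z-scores, C statistic, permutation p-values,
#' classification and null-ensemble uncertainty. Each cell's random stream is
#' seeded deterministically from the master seed and the cell index, so
#' results do not depend on visiting order or on the number of workers.
#'
#' @param pair A [change_pair()].
#' @param d Window side in metres; must be a multiple of the resolution.
#' @param nsim Monte Carlo replicates per cell (default 5000).
#' @param alpha Significance level (default 0.05).
#' @param seed Master integer seed (required).
#' @param min_count Edge-correction threshold passed to [edge_correct()].
#' @param workers Parallel workers via [parallel::mclapply()] (forked
#'   processes; results are identical to the serial run).
#' @param at Optional two-column matrix or data frame of `(row, col)` cell
#'   indices to analyze instead of every valid cell -- e.g. a spatially
#'   thinned subset whose windows do not overlap, which makes the per-cell
#'   tests independent (useful for calibration studies). Cell seeds are
#'   derived from the master seed and the cell's position in `at`.
#' @return An object of class `dixon_map`; `tidy()` returns the per-cell
#'   tibble, `glance()` a one-row summary, `autoplot()` maps of the index,
#'   classification, p-values or uncertainty.
#' @export
local_dixon_map <- function(pair, d, nsim = 5000, alpha = 0.05, seed,
                            min_count = 4, workers = 1, at = NULL) {
  stopifnot(inherits(pair, "change_pair"))
  if (missing(seed)) abort("`seed` is required for a reproducible run")
  res <- pair$resolution
  if (abs(d / res - round(d / res)) > 1e-9) {
    abort(sprintf("window size d = %g m is not a multiple of the resolution (%g m)",
                  d, res))
  }
  radius <- window_radius(d, res)
  ci <- pair_counts(pair)
  ok <- !is.na(pair$t1) & !is.na(pair$t2)
  if (is.null(at)) {
    idx <- which(ok, arr.ind = TRUE)
  } else {
    idx <- as.matrix(as.data.frame(at)[, 1:2])
    storage.mode(idx) <- "integer"
    bad <- idx[, 1] < 1 | idx[, 1] > nrow(ok) | idx[, 2] < 1 |
      idx[, 2] > ncol(ok)
    bad[!bad] <- !ok[idx[!bad, , drop = FALSE]]
    if (any(bad)) abort("`at` contains cells outside the grid or on nodata")
  }
  n <- nrow(idx)
  if (n == 0) abort("no valid cells to analyze")
  set.seed(seed)
  cell_seeds <- sample.int(2147483646L, n)
  pmf_cache <- new.env(parent = emptyenv())
  one_cell <- function(ii) {
    i <- idx[ii, 1]; j <- idx[ii, 2]
    cc <- scan_cell_counts(ci, i, j, radius, min_count)
    tab <- as_contingency_table(cc$naa, cc$nab, cc$nba, cc$nbb)
    eff_d <- d + 2 * res * cc$rings
    if (cc$flagged) {
      st <- list(Saa = NA_real_, z_aa = NA_real_, z_bb = NA_real_,
                 r = NA_real_, C = NA_real_, p_C = NA_real_,
                 p_zaa = NA_real_, p_zbb = NA_real_, width = NA_real_,
                 label = "undefined")
    } else {
      key <- paste0(tab$m, "_", tab$Na)
      pmf <- pmf_cache[[key]]
      if (is.null(pmf)) {
        pmf <- naa_pmf(tab$m, tab$Na)
        pmf_cache[[key]] <- pmf
      }
      st <- cell_stats(tab, nsim, cell_seeds[ii], alpha, pmf = pmf)
    }
    c(list(row = i, col = j, m = tab$m, effective_d = eff_d,
           truncated = cc$truncated, flagged = cc$flagged,
           Naa = tab$Naa, Nab = tab$Nab, Nba = tab$Nba, Nbb = tab$Nbb,
           Na = tab$Na, Nb = tab$Nb, cell_seed = cell_seeds[ii]), st)
  }
  rows <- if (workers > 1) {
    parallel::mclapply(seq_len(n), one_cell, mc.cores = workers)
  } else {
    lapply(seq_len(n), one_cell)
  }
  cells <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  cells$x <- pair$origin[1] + (cells$col - 0.5) * res
  cells$y <- pair$origin[2] + (nrow(pair$t1) - cells$row + 0.5) * res
  cells$t1 <- pair$t1[cbind(cells$row, cells$col)]
  cells$t2 <- pair$t2[cbind(cells$row, cells$col)]
  max_w <- suppressWarnings(max(cells$width, na.rm = TRUE))
  cells$uncertainty <- if (is.finite(max_w) && max_w > 0) {
    cells$width / max_w
  } else {
    ifelse(is.na(cells$width), NA_real_, 0)
  }
  cells <- dplyr::arrange(cells, .data$row, .data$col)
  cells <- dplyr::relocate(cells, "row", "col", "x", "y", "t1", "t2")
  structure(
    list(cells = cells, d = d, nsim = nsim, alpha = alpha, seed = seed,
         min_count = min_count, resolution = res, origin = pair$origin,
         dim = dim(pair$t1), target_class = pair$target_class,
         n_undefined = sum(cells$label == "undefined")),
    class = "dixon_map"
  )
}

#' @export
print.dixon_map <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<dixon_map> d = %g m, %d cells analyzed (nsim = %d, alpha = %g, seed = %d)\n",
              x$d, g$n_cells, x$nsim, x$alpha, x$seed))
  cat(sprintf("  significant: %d (%.1f%%); undefined: %d\n",
              g$n_significant, 100 * g$prop_significant, g$n_undefined))
  print(table(x$cells$label))
  invisible(x)
}

#' @describeIn local_dixon_map Per-cell results as a tibble.
#' @param x,object A `dixon_map`.
#' @param ... Unused.
#' @export
tidy.dixon_map <- function(x, ...) x$cells

#' @describeIn local_dixon_map One-row summary of a map.
#' @export
glance.dixon_map <- function(x, ...) {
  sig <- !is.na(x$cells$p_C) & x$cells$p_C < x$alpha
  tibble::tibble(
    d = x$d, n_cells = nrow(x$cells), n_undefined = x$n_undefined,
    n_significant = sum(sig), prop_significant = mean(sig),
    n_segregation = sum(x$cells$label == "segregation"),
    n_association = sum(x$cells$label == "association"),
    nsim = x$nsim, alpha = x$alpha, seed = x$seed
  )
}

#' @describeIn local_dixon_map Map a layer with ggplot2 (`type` one of
#'   `"saa"`, `"label"`, `"uncertainty"`, `"p_c"`).
#' @param type Layer to draw.
#' @export
autoplot.dixon_map <- function(object, type = c("saa", "label", "uncertainty", "p_c"),
                               ...) {
  type <- match.arg(type)
  cells <- object$cells
  base <- ggplot2::ggplot(cells, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Easting (m)", y = "Northing (m)") +
    ggplot2::theme_minimal()
  switch(
    type,
    saa = base +
      ggplot2::geom_raster(ggplot2::aes(fill = .data$Saa)) +
      ggplot2::scale_fill_gradient2(low = "firebrick", mid = "grey95",
                                    high = "navy", midpoint = 0,
                                    name = "Saa"),
    label = base +
      ggplot2::geom_raster(ggplot2::aes(fill = .data$label)) +
      ggplot2::scale_fill_manual(
        values = c(segregation = "navy", association = "firebrick",
                   random = "grey85", undefined = "goldenrod"),
        name = NULL),
    uncertainty = base +
      ggplot2::geom_raster(ggplot2::aes(fill = .data$uncertainty)) +
      ggplot2::scale_fill_viridis_c(name = "Uncertainty", limits = c(0, 1)),
    p_c = base +
      ggplot2::geom_raster(ggplot2::aes(fill = .data$p_C)) +
      ggplot2::scale_fill_viridis_c(name = "p(C)", direction = -1)
  )
}

#' Choose the window size with the most significant cells
#'
#' Runs [local_dixon_map()] for every candidate window and returns the
#' candidate with the largest number of cells whose C statistic is
#' significant at `alpha`. Ties are broken in favour of the candidate whose
#' windows needed the least mean edge-correction enlargement -- i.e. the
#' window size closest to the one actually analyzed -- and then the smaller
#' window. (At 50 m resolution a 100 m window can never satisfy the
#' edge-correction counts and is always enlarged to at least 250 m, so 100 m
#' and 250 m candidates produce identical maps; the enlargement-aware
#' tie-break resolves that degeneracy in favour of the undistorted window.)
#'
#' @inheritParams local_dixon_map
#' @param candidates Candidate window sides in metres (each a multiple of the
#'   resolution).
#' @param changed_only Count only cells that changed between the two dates
#'   (default `FALSE`: all significant cells are counted).
#' @param keep_best Keep the full `dixon_map` of the winning candidate.
#' @return Object of class `window_selection`: `best_d`, `candidate_counts`
#'   (tibble `d` / `n_significant`), and `best_map` when `keep_best`.
#' @export
select_window <- function(pair, candidates, nsim = 5000, alpha = 0.05, seed,
                          min_count = 4, workers = 1, changed_only = FALSE,
                          keep_best = TRUE) {
  if (length(candidates) < 1) abort("at least one candidate window is required")
  if (missing(seed)) abort("`seed` is required for a reproducible run")
  res <- pair$resolution
  bad <- candidates[abs(candidates / res - round(candidates / res)) > 1e-9]
  if (length(bad) > 0) {
    abort(paste0("candidate windows must be multiples of the resolution (",
                 res, " m): ", paste(bad, collapse = ", ")))
  }
  candidates <- sort(candidates)
  maps <- vector("list", length(candidates))
  counts <- integer(length(candidates))
  enlargement <- numeric(length(candidates))
  for (i in seq_along(candidates)) {
    inform(sprintf("select_window: d = %g m", candidates[i]))
    mp <- local_dixon_map(pair, candidates[i], nsim = nsim, alpha = alpha,
                          seed = seed, min_count = min_count, workers = workers)
    sig <- !is.na(mp$cells$p_C) & mp$cells$p_C < alpha
    if (changed_only) sig <- sig & mp$cells$t1 != mp$cells$t2
    counts[i] <- sum(sig)
    enlargement[i] <- mean(mp$cells$effective_d - candidates[i])
    maps[[i]] <- mp
  }
  tied <- which(counts == max(counts))
  least <- tied[enlargement[tied] <= min(enlargement[tied]) + 1e-9]
  best_i <- least[1] # remaining ties -> smaller d (sorted)
  structure(
    list(best_d = candidates[best_i],
         candidate_counts = tibble::tibble(d = candidates,
                                           n_significant = counts,
                                           mean_enlargement = enlargement),
         best_map = if (keep_best) maps[[best_i]] else NULL,
         changed_only = changed_only, nsim = nsim, alpha = alpha, seed = seed),
    class = "window_selection"
  )
}

#' @export
print.window_selection <- function(x, ...) {
  cat(sprintf("<window_selection> best d = %g m (alpha = %g, nsim = %d)\n",
              x$best_d, x$alpha, x$nsim))
  print(as.data.frame(x$candidate_counts), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.window_selection <- function(x, ...) x$candidate_counts

#' Area accounting of significant losses and gains
#'
#' Loss cells are target at the first date and other at the second
#' (`1 -> 0`); gain cells the reverse. A loss is counted significant when its
#' cell is classified `association`, a gain when classified `segregation`
#' (classification already encodes `p_C < alpha`). Areas use
#' `cells * resolution^2 / 10^4` hectares.
#'
#' @param map A [local_dixon_map()] result.
#' @return Tibble with one row per category (`loss`, `gain`): total and
#'   significant cell counts, hectares and the percent significant.
#' @export
area_summary <- function(map) {
  stopifnot(inherits(map, "dixon_map"))
  ha <- map$resolution^2 / 1e4
  cells <- map$cells
  summarize_cat <- function(sel, sig_label, name) {
    tot <- sum(sel)
    sig <- sum(sel & cells$label == sig_label)
    tibble::tibble(category = name, cells_total = tot, cells_significant = sig,
                   ha_total = tot * ha, ha_significant = sig * ha,
                   pct_significant = if (tot > 0) 100 * sig / tot else NA_real_)
  }
  dplyr::bind_rows(
    summarize_cat(cells$t1 == 1 & cells$t2 == 0, "association", "loss"),
    summarize_cat(cells$t1 == 0 & cells$t2 == 1, "segregation", "gain")
  )
}
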