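#' Dixon's spatio-temporal segregation index Saa
#'
#' Natural-log odds ratio comparing the observed persistence odds of the
#' target class, `Naa / Nab`, with the odds expected under random labelling
#' of the `N = 2m` space-time labels in the window, `(Na - 1) / Nb`:
#' `Saa = ln[(Naa / Nab) / ((Na - 1) / Nb)]`. Positive values indicate
#' segregation (persistence/expansion of the target class beyond random
#' expectation), negative values association (erosion).
#'
#' @param table A [contingency_table()], normally produced after
#'   [edge_correct()] so that `Naa > 0` and `Nab > 0`.
#' @return The index value; `NaN`/`Inf` when the table is degenerate (callers
#'   label such cells `undefined`).
#' @examples
#' saa(as_contingency_table(4, 6, 1, 7))   # exactly 0
#' saa(as_contingency_table(30, 5, 3, 12)) # about 1.053
#' @export
saa <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  log((table$Naa / table$Nab) / ((table$Na - 1) / table$Nb))
}

# ---- exact permutation distribution of the table -------------------------
#
# Random labelling permutes the N = 2m space-time labels (Na targets) across
# the 2m slots while keeping the cell <-> cell temporal pairing fixed. The
# whole table is then determined by Naa and the Nab/Nba split of the
# D = Na - 2 Naa discordant cells:
#   P(Naa = k)  proportional to  C(m,k) C(m-k, Na-2k) 2^(Na-2k)
#   Nab | Naa   ~ Binomial(D, 1/2)    (each discordant cell's orientation)
#   Nbb = m - Na + Naa,  Nba = D - Nab.
naa_pmf <- function(m, Na) {
  N <- 2L * m
  if (Na < 0 || Na > N) abort("need 0 <= Na <= 2m")
  kmin <- max(0L, Na - m)
  kmax <- Na %/% 2L
  k <- kmin:kmax
  lp <- lchoose(m, k) + lchoose(m - k, Na - 2 * k) + (Na - 2 * k) * log(2) -
    lchoose(N, Na)
  p <- exp(lp - max(lp))
  list(k = k, p = p / sum(p))
}

# nsim draws of (Naa, Nab, Nba, Nbb); uses the current RNG stream
sample_null_tables <- function(m, Na, nsim, pmf = NULL) {
  pmf <- pmf %||% naa_pmf(m, Na)
  cum <- cumsum(pmf$p)
  i <- findInterval(runif(nsim), cum) + 1L
  i[i > length(pmf$k)] <- length(pmf$k)
  naa <- pmf$k[i]
  D <- Na - 2L * naa
  nab <- rbinom(nsim, D, 0.5)
  list(Naa = naa, Nab = nab, Nba = D - nab, Nbb = m - Na + naa)
}

#' Null moments of Naa and Nbb under random labelling
#'
#' Expectation and variance of the persistence counts when the `N = 2m`
#' space-time labels of a window are permuted uniformly (temporal pairing
#' fixed). The closed form follows from the matching structure -- each cell is
#' one temporal pair of label slots, so
#' `E(Naa) = m Na (Na-1) / (N (N-1))` and the variance follows from the
#' pairwise slot-overlap probabilities. `method = "enumerate"` instead sums
#' over the exact distribution of `Naa` (available for any `m`, used as an
#' independent check and in tests).
#'
#' @param table A [contingency_table()] (only `m` and `Na` are used), or an
#'   integer `m` if `Na` is supplied.
#' @param Na Total target labels over both dates (when `table` is numeric).
#' @param method `"closed_form"` (default) or `"enumerate"`.
#' @return List with `E_Naa`, `Var_Naa`, `E_Nbb`, `Var_Nbb`. The identity
#'   `Nbb = Naa + m - Na` makes the Nbb moments shifts of the Naa ones.
#' @examples
#' exact_null_moments(3, Na = 4)$E_Naa # 3 * 4 * 3 / (6 * 5) = 1.2
#' @export
exact_null_moments <- function(table, Na = NULL,
                               method = c("closed_form", "enumerate")) {
  method <- match.arg(method)
  if (inherits(table, "contingency_table")) {
    m <- table$m; Na <- table$Na
  } else {
    m <- as.integer(table)
    if (is.null(Na)) abort("supply `Na` when `table` is a cell count")
  }
  N <- 2 * m
  if (method == "closed_form") {
    if (Na < 2 || m < 1) {
      E <- if (m >= 1 && Na >= 2) m * Na * (Na - 1) / (N * (N - 1)) else 0
      return(list(E_Naa = E, Var_Naa = 0, E_Nbb = E + m - Na, Var_Nbb = 0))
    }
    p2 <- Na * (Na - 1) / (N * (N - 1))
    p4 <- if (N >= 4) {
      Na * (Na - 1) * (Na - 2) * (Na - 3) / (N * (N - 1) * (N - 2) * (N - 3))
    } else 0
    E <- m * p2
    V <- m * p2 * (1 - p2) + m * (m - 1) * (p4 - p2^2)
  } else {
    pmf <- naa_pmf(m, Na)
    E <- sum(pmf$k * pmf$p)
    V <- sum((pmf$k - E)^2 * pmf$p)
  }
  list(E_Naa = E, Var_Naa = max(V, 0), E_Nbb = E + m - Na, Var_Nbb = max(V, 0))
}

#' Monte Carlo null ensemble under random labelling
#'
#' Permutes the `N = 2m` space-time labels of the window uniformly at random
#' (label totals `Na`, `Nb` and the temporal cell pairing fixed), rebuilds the
#' contingency table for each replicate and records `(Naa, Nbb, Saa, C)`.
#' Sampling goes through the exact combinatorial law of the permuted table
#' (see [exact_null_moments()]), which is what a label-vector shuffle
#' converges to, at O(nsim) cost per window. Moments and the Naa-Nbb null
#' correlation `r` are estimated from the replicates.
#'
#' @param window A [extract_window()]/[edge_correct()] window.
#' @param pair The [change_pair()].
#' @param nsim Number of replicates (>= 2).
#' @param seed Integer seed for this window's random stream.
#' @return Object of class `null_ensemble`: `sims` (tibble with `Naa`, `Nab`,
#'   `Nba`, `Nbb`, `Saa`, `z_aa`, `z_bb`, `C`), `moments` (list `E_Naa`,
#'   `Var_Naa`, `E_Nbb`, `Var_Nbb`, `r`), `table` (observed), `nsim`, `seed`,
#'   `degenerate` (zero null variance).
#' @export
null_ensemble <- function(window, pair, nsim, seed) {
  stopifnot(inherits(window, "dixon_window"))
  if (nsim < 2) abort("nsim must be at least 2")
  tab <- contingency_table(window, pair)
  ens <- null_ensemble_from_table(tab, nsim = nsim, seed = seed)
  ens
}

# wraps the lean numeric core (null_sims, R/scan.R) into the user-facing
# ensemble object; both paths therefore produce identical numbers
null_ensemble_from_table <- function(tab, nsim, seed, pmf = NULL) {
  ns <- null_sims(tab, nsim, seed, pmf = pmf)
  structure(
    list(
      sims = tibble::tibble(Naa = ns$sims$Naa, Nab = ns$sims$Nab,
                            Nba = ns$sims$Nba, Nbb = ns$sims$Nbb,
                            Saa = ns$Saa, z_aa = ns$z_aa, z_bb = ns$z_bb,
                            C = ns$C),
      moments = ns$moments,
      table = tab, nsim = nsim, seed = seed, degenerate = ns$degenerate
    ),
    class = "null_ensemble"
  )
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble> %d random-labelling replicates (seed %d)\n",
              x$nsim, x$seed))
  cat(sprintf("  window: m = %d, Na = %d, Nb = %d\n",
              x$table$m, x$table$Na, x$table$Nb))
  if (x$degenerate) {
    cat("  degenerate: no variability under the null\n")
  } else {
    cat(sprintf("  E(Naa) = %.3f, Var(Naa) = %.3f, r(Naa, Nbb) = %.6f\n",
                x$moments$E_Naa, x$moments$Var_Naa, x$moments$r))
  }
  invisible(x)
}

#' Standardized deviations of the persistence counts
#'
#' `z_aa = (Naa - E(Naa)) / sqrt(Var(Naa))` and analogously `z_bb`, with
#' moments estimated from the Monte Carlo null ensemble.
#'
#' @param table Observed [contingency_table()].
#' @param ensemble A [null_ensemble()] for the same window.
#' @return List with `z_aa`, `z_bb` and `degenerate` (TRUE when the null
#'   variance is zero, in which case the z-scores are `NA`).
#' @export
z_scores <- function(table, ensemble) {
  stopifnot(inherits(table, "contingency_table"),
            inherits(ensemble, "null_ensemble"))
  mo <- ensemble$moments
  if (ensemble$degenerate || !is.finite(mo$Var_Naa) || mo$Var_Naa <= 0) {
    return(list(z_aa = NA_real_, z_bb = NA_real_, degenerate = TRUE))
  }
  list(z_aa = (table$Naa - mo$E_Naa) / sqrt(mo$Var_Naa),
       z_bb = (table$Nbb - mo$E_Nbb) / sqrt(mo$Var_Nbb),
       degenerate = FALSE)
}

#' Chi-square-type combination of the two z-scores
#'
#' Combines `z_aa` and `z_bb` accounting for their null correlation `r`:
#' for `|r| < 1` this is `(z_aa^2 + z_bb^2 - 2 r z_aa z_bb) / (1 - r^2)`,
#' a 2-df chi-square-type quadratic form. The implementation uses the
#' eigendecomposition of the correlation matrix,
#' `C = (z_aa + z_bb)^2 / (2 (1 + r)) + (z_aa - z_bb)^2 / (2 (1 - r))`,
#' and drops a term when its eigenvalue is numerically zero (generalized
#' inverse). In the spatio-temporal design the identity
#' `Nbb = Naa + m - Na` forces `r = 1`, where `C` degrades continuously to
#' `z_aa^2` (1 df); the Monte Carlo reference distribution is built from the
#' same statistic, so p-values remain exact either way.
#'
#' @param z_aa,z_bb Numeric vectors of z-scores.
#' @param r Null correlation between `Naa` and `Nbb`.
#' @return `C >= 0`, vectorized over the z-scores; `NA` when inputs are `NA`.
#' @examples
#' c_statistic(1, 1, 0)       # 2
#' c_statistic(2, -1, 0.5)    # 9.333...
#' c_statistic(1.7, 1.7, 1)   # falls back to z^2
#' @export
c_statistic <- function(z_aa, z_bb, r) {
  if (is.na(r)) return(rep(NA_real_, length(z_aa)))
  eps <- 1e-10
  e1 <- 1 + r
  e2 <- 1 - r
  t1 <- if (e1 > eps) (z_aa + z_bb)^2 / (2 * e1) else 0
  t2 <- if (e2 > eps) (z_aa - z_bb)^2 / (2 * e2) else 0
  t1 + t2
}

#' Monte Carlo p-value (add-one permutation estimator)
#'
#' `p = (1 + #\{sim >= observed\}) / (1 + nsim)`; upper tail. Two-sided tests
#' on z-scores pass `abs(observed)` against `abs(sims)`.
#'
#' @param observed Observed statistic.
#' @param sims Replicate values under the null.
#' @return p-value in `(0, 1]`.
#' @examples
#' mc_pvalue(10, rep(1, 999))           # 1/1000
#' @export
mc_pvalue <- function(observed, sims) {
  sims <- sims[!is.na(sims)]
  if (length(sims) < 1) abort("no simulated values")
  if (is.na(observed)) return(NA_real_)
  (1 + sum(sims >= observed)) / (1 + length(sims))
}

#' Classify a cell from its index value and C p-value
#'
#' Significant positive `Saa` means segregation (target persistence or
#' expansion beyond random labelling); significant negative `Saa` means
#' association (erosion of the target class); otherwise the cell is
#' consistent with random labelling. Non-finite inputs propagate as
#' `"undefined"`.
#'
#' @param Saa Index value.
#' @param p_C Monte Carlo p-value of the C statistic.
#' @param alpha Significance level (default 0.05).
#' @return One of `"segregation"`, `"association"`, `"random"`, `"undefined"`.
#' @export
classify_cell <- function(Saa, p_C, alpha = 0.05) {
  if (!is.finite(Saa) || !is.finite(p_C)) return("undefined")
  if (p_C < alpha && Saa > 0) "segregation"
  else if (p_C < alpha && Saa < 0) "association"
  else "random"
}

# 95% interquantile width of the replicate Saa values (finite replicates)
saa_interval_width <- function(ensemble, level = 0.95) {
  s <- ensemble$sims$Saa
  s <- s[is.finite(s)]
  if (length(s) < 2) return(NA_real_)
  lo <- (1 - level) / 2
  unname(diff(quantile(s, c(lo, 1 - lo))))
}

#' Standardized uncertainty score of one cell
#'
#' The raw uncertainty of a cell is the width of the central 95% interval of
#' the replicate `Saa` values in its null ensemble; the score standardizes it
#' by the maximum raw width over all analyzed cells, so the most uncertain
#' cell of a map scores 1 and a degenerate (constant) ensemble scores 0.
#'
#' @param ensemble A [null_ensemble()].
#' @param map_widths Numeric vector of raw interval widths of all analyzed
#'   cells (the map context used for standardization).
#' @return Score in `[0, 1]` (`NA` if the width cannot be computed).
#' @export
uncertainty_score <- function(ensemble, map_widths) {
  w <- saa_interval_width(ensemble)
  mx <- suppressWarnings(max(map_widths, na.rm = TRUE))
  if (!is.finite(w)) return(NA_real_)
  if (!is.finite(mx) || mx <= 0) return(0)
  w / mx
}

#' Full local analysis of a single cell
#'
#' Convenience wrapper chaining [extract_window()], [edge_correct()],
#' [saa()], the Monte Carlo null and the p-values for one cell; the same
#' computation [local_dixon_map()] performs map-wide.
#'
#' @inheritParams extract_window
#' @param nsim,seed,alpha,min_count As in [local_dixon_map()]; `seed` is the
#'   cell-level seed.
#' @return One-row tibble matching the columns of [tidy.dixon_map()]
#'   (without the map-standardized `uncertainty`).
#' @export
dixon_local <- function(pair, center, d, nsim = 5000, seed, alpha = 0.05,
                        min_count = 4) {
  if (missing(seed)) abort("`seed` is required")
  w <- extract_window(pair, center, d)
  ec <- edge_correct(w, pair, min_count = min_count)
  tab <- ec$table
  st <- if (ec$flagged) {
    list(Saa = NA_real_, z_aa = NA_real_, z_bb = NA_real_, r = NA_real_,
         C = NA_real_, p_C = NA_real_, p_zaa = NA_real_, p_zbb = NA_real_,
         width = NA_real_, label = "undefined")
  } else {
    cell_stats(tab, nsim, seed, alpha)
  }
  tibble::as_tibble(c(
    list(row = center[1], col = center[2], m = tab$m,
         effective_d = ec$window$effective_d, truncated = ec$window$truncated,
         flagged = ec$flagged, Naa = tab$Naa, Nab = tab$Nab, Nba = tab$Nba,
         Nbb = tab$Nbb, Na = tab$Na, Nb = tab$Nb, cell_seed = seed),
    st
  ))
}
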