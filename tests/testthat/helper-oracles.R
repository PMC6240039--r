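# Independent brute-force oracles used across the suite. Everything here
# works from first principles (explicit label vectors, exhaustive subsets)
# and never calls the package's samplers or pmf.

# change pair straight from two 0/1 matrices
pair_from <- function(t1, t2, resolution = 50) {
  as_change_pair(t1, t2, resolution = resolution)
}

# exhaustive enumeration of random labelling in a window of m cells with Na
# target labels among the N = 2m slots (slots 2i-1, 2i belong to cell i).
# Returns the joint distribution of (Naa, Nab) and its moments.
enumerate_labellings <- function(m, Na) {
  N <- 2L * m
  subsets <- utils::combn(N, Na)
  naa <- integer(ncol(subsets)); nab <- integer(ncol(subsets))
  for (s in seq_len(ncol(subsets))) {
    lab <- logical(N)
    lab[subsets[, s]] <- TRUE
    s1 <- lab[seq(1, N, by = 2)]  # date-1 slots
    s2 <- lab[seq(2, N, by = 2)]  # date-2 slots
    naa[s] <- sum(s1 & s2)
    nab[s] <- sum(s1 & !s2)
  }
  list(
    Naa = naa, Nab = nab,
    E_Naa = mean(naa), Var_Naa = mean((naa - mean(naa))^2),
    E_Nbb = mean(m - Na + naa),
    pmf = as.data.frame(table(Naa = naa), stringsAsFactors = FALSE)
  )
}

# brute-force window membership: cells with centre within the axis-aligned
# square of side d centred on the centre cell, valid cells only
brute_window_members <- function(pair, center, d) {
  res <- pair$resolution
  out <- NULL
  for (i in seq_len(nrow(pair$t1))) {
    for (j in seq_len(ncol(pair$t1))) {
      if (is.na(pair$t1[i, j])) next
      if (abs(i - center[1]) * res <= d / 2 + 1e-9 &&
          abs(j - center[2]) * res <= d / 2 + 1e-9) {
        out <- rbind(out, c(i, j))
      }
    }
  }
  out
}

# brute-force contingency counts over an explicit member list
brute_counts <- function(pair, members) {
  v1 <- pair$t1[members]; v2 <- pair$t2[members]
  c(naa = sum(v1 == 1 & v2 == 1), nab = sum(v1 == 1 & v2 == 0),
    nba = sum(v1 == 0 & v2 == 1), nbb = sum(v1 == 0 & v2 == 0))
}

# cells whose centres lie within `radius` metres of the centre cell,
# enumerated directly from the distance definition
brute_disc_cells <- function(n_rows, n_cols, row, col, radius, resolution) {
  hits <- 0L
  for (i in seq_len(n_rows)) for (j in seq_len(n_cols)) {
    if (sqrt((i - row)^2 + (j - col)^2) * resolution <= radius + 1e-9) {
      hits <- hits + 1L
    }
  }
  hits
}

# Jaccard overlap between a disc footprint and the connected component of
# association-labelled cells grown (4-neighbour flood fill) from the disc
cluster_jaccard <- function(map, row, col, radius) {
  cells <- tidy(map)
  nr <- map$dim[1]; nc <- map$dim[2]
  amat <- matrix(FALSE, nr, nc)
  amat[cbind(cells$row, cells$col)] <- cells$label == "association"
  dmat <- sqrt(outer((seq_len(nr) - row)^2, (seq_len(nc) - col)^2, "+")) *
    map$resolution <= radius + 1e-9
  comp <- amat & dmat
  repeat {
    grown <- comp
    grown[-1, ] <- grown[-1, ] | comp[-nr, ]
    grown[-nr, ] <- grown[-nr, ] | comp[-1, ]
    grown[, -1] <- grown[, -1] | comp[, -nc]
    grown[, -nc] <- grown[, -nc] | comp[, -1]
    grown <- grown & amat
    if (identical(grown, comp)) break
    comp <- grown
  }
  sum(comp & dmat) / sum(comp | dmat)
}

# small deterministic landscape with one converted disc on a random-labelling
# background (the detection fixture; see the methods vignette)
detection_fixture <- function(seed, n = 60, p = 0.45, radius = 250) {
  cfg <- sim_config(
    n_rows = n, n_cols = n, smoothing = 0, p_target = p, seed = seed,
    target_region = list(list(row = n / 2, col = n / 2, radius = radius)),
    patches = list(
      sim_patch(n / 2, n / 2, 10000, 1 - p, "loss"),
      sim_patch(n / 2, n / 2, 10000, p, "gain"),
      sim_patch(n / 2, n / 2, radius, 1, "loss")
    )
  )
  gen_patch_change_pair(cfg)
}
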