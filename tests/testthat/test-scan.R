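test_that("maps are reproducible and independent of worker count", {
  pr <- gen_null_pair(sim_config(15, 15, seed = 41))
  m1 <- local_dixon_map(pr, 250, nsim = 99, seed = 3)
  m2 <- local_dixon_map(pr, 250, nsim = 99, seed = 3)
  expect_identical(m1$cells, m2$cells)
  m3 <- local_dixon_map(pr, 250, nsim = 99, seed = 3, workers = 2)
  expect_identical(m1$cells, m3$cells)
  m4 <- local_dixon_map(pr, 250, nsim = 99, seed = 4)
  expect_false(identical(m1$cells$p_C, m4$cells$p_C))
})

test_that("the map scan reproduces the single-cell computation", {
  pr <- gen_null_pair(sim_config(12, 12, seed = 17))
  mp <- local_dixon_map(pr, 250, nsim = 199, seed = 23)
  for (i in c(1, 40, 100)) {
    row <- mp$cells[i, ]
    single <- dixon_local(pr, c(row$row, row$col), 250, nsim = 199,
                          seed = row$cell_seed)
    for (col in c("m", "Naa", "Nab", "Saa", "z_aa", "C", "p_C", "p_zaa",
                  "width", "label", "effective_d")) {
      expect_identical(single[[col]], row[[col]])
    }
  }
})

test_that("per-cell columns are internally consistent", {
  pr <- gen_null_pair(sim_config(15, 15, seed = 43))
  mp <- local_dixon_map(pr, 250, nsim = 199, seed = 13)
  cells <- tidy(mp)
  ok <- !is.na(cells$p_C)
  expect_true(all(cells$p_C[ok] > 0 & cells$p_C[ok] <= 1))
  expect_true(all(cells$C[ok] >= 0))
  expect_true(all(cells$Naa + cells$Nab + cells$Nba + cells$Nbb == cells$m))
  expect_true(all(cells$Na + cells$Nb == 2 * cells$m))
  expect_true(all(cells$effective_d >= mp$d))
  # classification recomputes from Saa and p_C
  expect_identical(cells$label,
                   mapply(classify_cell, cells$Saa, cells$p_C,
                          MoreArgs = list(alpha = mp$alpha)))
  # uncertainty is standardized to the map maximum
  expect_equal(max(cells$uncertainty, na.rm = TRUE), 1)
  expect_true(all(cells$uncertainty >= 0 & cells$uncertainty <= 1, na.rm = TRUE))
  # undefined cells are counted and excluded from significance
  expect_equal(mp$n_undefined, sum(cells$label == "undefined"))
})

test_that("a zero-change map is undefined everywhere", {
  m1 <- matrix(1L, 10, 10)
  pr <- as_change_pair(m1, m1)
  mp <- local_dixon_map(pr, 250, nsim = 99, seed = 2)
  expect_true(all(mp$cells$label == "undefined"))
  expect_equal(glance(mp)$n_significant, 0)
})

test_that("window selection counts, tie-breaks and validates candidates", {
  pr <- detection_fixture(seed = 11)
  expect_error(local_dixon_map(pr, 225, nsim = 9, seed = 1), "multiple")
  sel1 <- suppressMessages(
    select_window(pr, 250, nsim = 99, seed = 3, keep_best = FALSE))
  expect_equal(sel1$best_d, 250)
  expect_error(suppressMessages(select_window(pr, c(120, 250), nsim = 9, seed = 1)),
               "multiples")
  expect_error(select_window(pr, numeric(0), seed = 1), "at least one")

  sel <- suppressMessages(
    select_window(pr, c(100, 250), nsim = 199, seed = 3))
  # 100 m windows can never hold the required counts: identical analyses,
  # and the tie resolves to the window that was not edge-inflated
  expect_equal(sel$candidate_counts$n_significant[1],
               sel$candidate_counts$n_significant[2])
  expect_gt(sel$candidate_counts$mean_enlargement[1],
            sel$candidate_counts$mean_enlargement[2])
  expect_equal(sel$best_d, 250)
  # the chosen candidate attains the maximum count
  expect_equal(max(sel$candidate_counts$n_significant),
               sel$candidate_counts$n_significant[sel$candidate_counts$d == sel$best_d])
  expect_s3_class(sel$best_map, "dixon_map")
  expect_equal(sel$best_map$d, 250)
})

test_that("a converted disc surfaces as a significant association cluster", {
  pr <- detection_fixture(seed = 12)
  mp <- local_dixon_map(pr, 250, nsim = 199, seed = 5)
  cells <- tidy(mp)
  disc <- sqrt((cells$row - 30)^2 + (cells$col - 30)^2) * 50 <= 250 + 1e-9
  assoc <- cells$label == "association"
  # the cluster covers most of the footprint and stays anchored to it
  expect_gt(sum(disc & assoc) / sum(disc), 0.8)
  expect_gt(sum(disc & assoc) / sum(disc | assoc), 0.4)
  # mean index inside the disc is strongly negative
  expect_lt(mean(cells$Saa[disc], na.rm = TRUE), -0.5)
})

test_that("detection power is monotone in conversion intensity", {
  count_assoc <- function(conv) {
    n <- 40
    cfg <- sim_config(n, n, smoothing = 0, seed = 77,
                      target_region = list(list(row = 20, col = 20, radius = 250)),
                      patches = list(
                        sim_patch(20, 20, 10000, 0.55, "loss"),
                        sim_patch(20, 20, 10000, 0.45, "gain"),
                        sim_patch(20, 20, 250, conv, "loss")))
    pr <- gen_patch_change_pair(cfg)
    mp <- local_dixon_map(pr, 250, nsim = 199, seed = 5)
    cells <- tidy(mp)
    disc <- sqrt((cells$row - 20)^2 + (cells$col - 20)^2) * 50 <= 250 + 1e-9
    sum(cells$label[disc] == "association")
  }
  counts <- vapply(c(0.2, 0.5, 0.9), count_assoc, numeric(1))
  # non-decreasing within Monte Carlo error (allow one-cell slack)
  expect_true(all(diff(counts) >= -1))
  expect_gt(counts[3], counts[1])
})

test_that("area summary books loss and gain cells against their labels", {
  pr <- detection_fixture(seed = 14)
  mp <- local_dixon_map(pr, 250, nsim = 199, seed = 7)
  as_ <- area_summary(mp)
  expect_equal(as_$category, c("loss", "gain"))
  cells <- tidy(mp)
  expect_equal(as_$cells_total[1], sum(cells$t1 == 1 & cells$t2 == 0))
  expect_equal(as_$cells_significant[1],
               sum(cells$t1 == 1 & cells$t2 == 0 & cells$label == "association"))
  expect_equal(as_$cells_significant[2],
               sum(cells$t1 == 0 & cells$t2 == 1 & cells$label == "segregation"))
  # hectares: cells x resolution^2 / 1e4 at 50 m is a quarter hectare per cell
  expect_equal(as_$ha_total, as_$cells_total * 0.25)
  expect_equal(as_$ha_significant, as_$cells_significant * 0.25)
  expect_true(all(as_$cells_significant <= as_$cells_total))
})

test_that("thinned analysis restricts the scan to the requested cells", {
  pr <- gen_null_pair(sim_config(30, 30, seed = 55))
  at <- expand.grid(row = c(5, 15, 25), col = c(5, 15, 25))
  mp <- local_dixon_map(pr, 250, nsim = 99, seed = 1, at = at)
  expect_equal(nrow(mp$cells), 9)
  expect_setequal(mp$cells$row, c(5, 15, 25))
  expect_error(local_dixon_map(pr, 250, nsim = 99, seed = 1,
                               at = cbind(40, 1)),
               "outside")
})
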