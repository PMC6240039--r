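test_that("the segregation index evaluates the log odds ratio", {
  expect_equal(saa(as_contingency_table(4, 6, 1, 7)), 0)
  expect_equal(saa(as_contingency_table(30, 5, 3, 12)),
               log(6 / (67 / 32)), tolerance = 1e-12)
  expect_equal(saa(as_contingency_table(30, 5, 3, 12)), 1.0528, tolerance = 1e-4)
  expect_equal(saa(as_contingency_table(2, 10, 1, 12)), log(0.5), tolerance = 1e-12)
  expect_equal(saa(as_contingency_table(2, 10, 1, 12)), -0.6931, tolerance = 1e-4)
})

test_that("Saa is zero exactly when Naa * Nb equals Nab * (Na - 1)", {
  set.seed(21)
  for (k in 1:20) {
    tab <- as_contingency_table(sample(1:9, 1), sample(1:9, 1),
                                sample(0:9, 1), sample(1:9, 1))
    s <- saa(tab)
    if (tab$Naa * tab$Nb == tab$Nab * (tab$Na - 1)) {
      expect_equal(s, 0)
    } else {
      expect_true(abs(s) > 0)
    }
  }
})

test_that("closed-form null moments match exhaustive enumeration", {
  for (m in 2:5) {
    for (Na in 1:(2 * m - 1)) {
      or <- enumerate_labellings(m, Na)
      cf <- exact_null_moments(m, Na = Na)
      en <- exact_null_moments(m, Na = Na, method = "enumerate")
      expect_equal(cf$E_Naa, or$E_Naa, tolerance = 1e-12)
      expect_equal(cf$Var_Naa, or$Var_Naa, tolerance = 1e-12)
      expect_equal(en$E_Naa, or$E_Naa, tolerance = 1e-12)
      expect_equal(en$Var_Naa, or$Var_Naa, tolerance = 1e-12)
      expect_equal(cf$E_Nbb, or$E_Nbb, tolerance = 1e-12)
    }
  }
  # frozen reference value: m = 3, Na = 4 gives E(Naa) = 3*4*3/(6*5)
  expect_equal(exact_null_moments(3, Na = 4)$E_Naa, 1.2)
  # degenerate corners
  expect_equal(exact_null_moments(5, Na = 0)$E_Naa, 0)
  expect_equal(exact_null_moments(5, Na = 0)$Var_Naa, 0)
  expect_equal(exact_null_moments(1, Na = 2)$E_Naa, 1)
  expect_equal(exact_null_moments(1, Na = 2)$Var_Naa, 0)
})

test_that("the null ensemble reproduces the enumerated labelling law", {
  # m = 3 window holding Na = 4 target labels across the two dates
  pr <- pair_from(matrix(c(1L, 1L, 0L), 1), matrix(c(1L, 0L, 1L), 1))
  w <- extract_window(pr, c(1, 2), 150)
  tab <- contingency_table(w, pr)
  expect_equal(tab$m, 3); expect_equal(tab$Na, 4)
  ens <- null_ensemble(w, pr, nsim = 4000, seed = 99)
  or <- enumerate_labellings(3, 4)
  se <- sqrt(or$Var_Naa / 4000)
  expect_lt(abs(mean(ens$sims$Naa) - or$E_Naa), 3 * se)
  expect_lt(abs(mean(ens$sims$Nbb) - or$E_Nbb), 3 * se)
  expect_equal(or$E_Naa, 1.2)
  # Nab checks the discordant-orientation half of the law
  expect_lt(abs(mean(ens$sims$Nab) - mean(or$Nab)), 4 * sd(or$Nab) / sqrt(4000))
  # moments slot is recomputable from the replicates
  expect_equal(ens$moments$E_Naa, mean(ens$sims$Naa))
  expect_equal(ens$moments$Var_Naa, var(ens$sims$Naa))
})

test_that("ensemble replicate tables close and the Naa-Nbb identity holds", {
  set.seed(31)
  t1 <- matrix(rbinom(49, 1, 0.5), 7); t2 <- matrix(rbinom(49, 1, 0.5), 7)
  pr <- pair_from(t1, t2)
  w <- extract_window(pr, c(4, 4), 250)
  tab <- contingency_table(w, pr)
  ens <- null_ensemble(w, pr, nsim = 300, seed = 5)
  with(ens$sims, {
    expect_true(all(Naa + Nab + Nba + Nbb == tab$m))
    expect_true(all(2 * Naa + Nab + Nba == tab$Na))
    expect_true(all(Nbb - Naa == tab$m - tab$Na))
  })
  # the margin identity forces perfect null correlation of Naa and Nbb
  expect_equal(ens$moments$r, 1, tolerance = 1e-9)
})

test_that("same seed gives identical ensembles; degenerate windows are flagged", {
  pr <- pair_from(matrix(rbinom(25, 1, 0.5), 5), matrix(rbinom(25, 1, 0.5), 5))
  w <- extract_window(pr, c(3, 3), 250)
  e1 <- null_ensemble(w, pr, nsim = 200, seed = 7)
  e2 <- null_ensemble(w, pr, nsim = 200, seed = 7)
  expect_identical(e1$sims, e2$sims)
  expect_error(null_ensemble(w, pr, nsim = 1, seed = 7), "at least 2")

  all1 <- pair_from(matrix(1L, 4, 4), matrix(1L, 4, 4))
  wa <- extract_window(all1, c(2, 2), 150)
  ea <- null_ensemble(wa, all1, nsim = 100, seed = 1)
  expect_true(ea$degenerate)
  expect_true(all(ea$sims$Naa == contingency_table(wa, all1)$m))
  expect_true(var(ea$sims$Naa) == 0)
})

test_that("z-scores standardize against the ensemble moments", {
  fake <- structure(list(moments = list(E_Naa = 1.2, Var_Naa = 0.36,
                                        E_Nbb = 3.2, Var_Nbb = 0.36, r = 1),
                         degenerate = FALSE),
                    class = "null_ensemble")
  tab <- as_contingency_table(3, 1, 1, 4)  # m = 9... counts only read directly
  zz <- z_scores(tab, fake)
  expect_equal(zz$z_aa, (3 - 1.2) / 0.6)
  fake0 <- fake; fake0$degenerate <- TRUE
  expect_true(z_scores(tab, fake0)$degenerate)
  expect_true(is.na(z_scores(tab, fake0)$z_aa))
})

test_that("the C statistic matches the correlated quadratic form", {
  expect_equal(c_statistic(0, 0, 0.3), 0)
  expect_equal(c_statistic(1, 1, 0), 2)
  expect_equal(c_statistic(2, -1, 0.5), 7 / 0.75, tolerance = 1e-12)
  # generalized-inverse limit at |r| = 1 degrades to z^2
  expect_equal(c_statistic(1.7, 1.7, 1), 1.7^2)
  expect_equal(c_statistic(-2, 2, -1), 4)
  # C >= 0 and zero only at the null point
  set.seed(8)
  for (k in 1:25) {
    z1 <- rnorm(1); z2 <- rnorm(1); r <- runif(1, -0.95, 0.95)
    C <- c_statistic(z1, z2, r)
    expect_gte(C, 0)
    if (abs(z1) > 1e-8 || abs(z2) > 1e-8) expect_gt(C, 0)
  }
})

test_that("Monte Carlo p-values use the add-one permutation estimator", {
  expect_equal(mc_pvalue(10, rep(1, 999)), 1 / 1000)
  sims <- c(rep(1, 950), rep(3, 49))
  expect_equal(mc_pvalue(2, sims), 0.05)
  expect_equal(mc_pvalue(0, abs(rnorm(99))), 1)
  expect_error(mc_pvalue(1, numeric(0)), "no simulated")
  p <- mc_pvalue(0.5, runif(99))
  expect_gt(p, 0); expect_lte(p, 1)
})

test_that("cells classify by index sign and C significance", {
  expect_equal(classify_cell(1.2, 0.01), "segregation")
  expect_equal(classify_cell(-0.8, 0.03), "association")
  expect_equal(classify_cell(2.0, 0.40), "random")
  expect_equal(classify_cell(NaN, 0.01), "undefined")
  expect_equal(classify_cell(1, NA), "undefined")
  expect_equal(classify_cell(0, 0.01), "random")
})

test_that("uncertainty is the 95% replicate interval standardized to the map", {
  fake_ens <- function(saa) {
    structure(list(sims = tibble::tibble(Saa = saa)), class = "null_ensemble")
  }
  expect_equal(uncertainty_score(fake_ens(rep(2, 500)), map_widths = c(0, 4)), 0)
  spread <- quantile(1:1000 / 100, c(0.025, 0.975))
  e <- fake_ens(1:1000 / 100)
  w <- unname(diff(spread))
  expect_equal(uncertainty_score(e, map_widths = c(w, 2 * w)), 0.5)
  expect_equal(uncertainty_score(e, map_widths = c(w / 2, w)), 1)
})
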