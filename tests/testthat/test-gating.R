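test_that("population limits, normalization and symmetry hold", {
  hp <- fixture_params("human-20s")
  # zero-ligand limit: f_open = L / (1 + L)
  expect_equal(populations(0, hp)$f_open, 4e-6 / (1 + 4e-6), tolerance = 1e-9)
  # fractions sum to 1 and stay in (0, 1) over a wide grid
  x <- logspace(1e-9, 1e-2, 60)
  pop <- populations(x, hp)
  expect_equal(pop$f_open + pop$f_closed, rep(1, 60))
  expect_true(all(pop$f_open > 0 & pop$f_open < 1))
  # K_o > K_c: monotone non-decreasing open fraction
  expect_true(all(diff(pop$f_open) >= 0))
  # K_o = K_c: ligand cannot shift the equilibrium
  sym <- two_state_params(K_o = 1e5, K_c = 1e5, k_o = 1e6, k_c = 1e2,
                          k_off = 0.5, L = 0.3, n = 3)
  expect_equal(populations(x, sym)$f_open, rep(0.3 / 1.3, 60),
               tolerance = 1e-12)
  # overflow-safe at extreme concentrations; saturation limit is
  # L (K_o/K_c)^n / (1 + L (K_o/K_c)^n), not exactly 1
  sat <- 4e-6 * (1.8e7 / 7e3)^3
  expect_equal(populations(1e6, hp)$f_open, sat / (1 + sat), tolerance = 1e-9)
  expect_error(populations(-1, hp), ">= 0")
  expect_error(populations(1e-6, fixture_params("alpha3dn")), "cooperative")
})

test_that("k_obs values match direct arithmetic on the printed constants", {
  ap <- fixture_params("alpha3dn")
  expect_equal(kobs_model(5e-6, ap), 19.5)          # 2.5e6 * 5e-6 + 7.0
  hp <- fixture_params("human-20s")
  expect_equal(kobs_model(1e-10, hp), 0.22, tolerance = 1e-4)
  got <- kobs_model(5e-6, hp)
  want <- oracle_kobs(5e-6, 1.8e7, 7e3, 2.8e6, 1.3e2, 0.22, 4e-6, 3)
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(round(got, 1), 10.5)
  # the open fraction driving it is ~0.73 at 5 uM
  expect_equal(populations(5e-6, hp)$f_open,
               oracle_f_open(5e-6, 1.8e7, 7e3, 4e-6, 3), tolerance = 1e-12)
  expect_error(kobs_model(0, hp), "> 0")
})

test_that("the cooperative law degenerates to the bimolecular one", {
  p <- two_state_params(K_o = 2e5, K_c = 2e5, k_o = 3e6, k_c = 3e6,
                        k_off = 1.5, L = 0.05, n = 3)
  set.seed(5)
  x <- 10^runif(40, -8, -3)
  expect_equal(kobs_model(x, p, mode = "cooperative"),
               3e6 * x + 1.5, tolerance = 1e-10)
})

test_that("asymptotes of the cooperative law bracket the state rate constants", {
  hp <- fixture_params("human-20s")
  # x -> 0: slope k_c + k_o L/(1+L) -- essentially k_c once L << 1
  x_lo <- c(1e-10, 2e-10)
  slope_lo <- diff(kobs_model(x_lo, hp)) / diff(x_lo)
  expect_equal(slope_lo, hp$k_c + hp$k_o * hp$L / (1 + hp$L),
               tolerance = 0.01)
  # x -> inf: slope -> k_o as the open state saturates
  x_hi <- c(1e-2, 2e-2)
  slope_hi <- diff(kobs_model(x_hi, hp)) / diff(x_hi)
  expect_equal(slope_hi, hp$k_o, tolerance = 1e-4)
})

test_that("population curves locate the open/closed crossover", {
  hp <- fixture_params("human-20s")
  pc <- population_curves(hp, logspace(1e-7, 1e-4, 80))
  # closed-form oracle: L^(1/n) (1 + K_o x) = 1 + K_c x
  r <- (4e-6)^(1 / 3)
  x_star <- (1 - r) / (r * 1.8e7 - 7e3)
  expect_equal(pc$crossover, x_star, tolerance = 1e-6)
  expect_equal(pc$crossover * 1e6, 3.53, tolerance = 0.01)  # ~3.5 uM
  # grid that does not bracket the crossover reports absence
  none <- population_curves(hp, logspace(1e-8, 1e-7, 10))
  expect_true(is.na(none$crossover))
  # L >= 1 with K_o > K_c keeps the open state dominant everywhere
  op <- two_state_params(K_o = 1e6, K_c = 1e3, k_o = 1e6, k_c = 1e2,
                         k_off = 1, L = 2, n = 3)
  expect_true(all(population_curves(op, logspace(1e-8, 1e-3, 30))$curve$f_open
                  >= 2 / 3 - 1e-12))
})

test_that("detailed-balance report reproduces the printed ratios and flags abuse", {
  ap <- consistency_report(fixture_params("alpha3dn"))
  expect_equal(ap$ratio[ap$state == "open"], (2.5e6 / 7.0) / 3.6e5,
               tolerance = 1e-9)
  expect_equal(ap$ratio[ap$state == "open"], 0.99, tolerance = 0.01)
  expect_false(any(ap$flag))
  hu <- consistency_report(fixture_params("human-20s"))
  expect_equal(hu$ratio[hu$state == "open"], (2.8e6 / 0.22) / 1.8e7,
               tolerance = 1e-9)
  expect_false(hu$flag[hu$state == "open"])
  bad <- two_state_params(K_o = 100 * 2.5e6 / 7.0, k_o = 2.5e6, k_off = 7.0,
                          n = 1)
  expect_true(consistency_report(bad)$flag[1])
})

test_that("bimolecular fits recover slope and intercept from noisy series", {
  ser <- simulate_fixture("alpha3dn", seed = 12)
  f <- fit_kobs(ser, "bimolecular")
  expect_lt(abs(f$params$k_o / 2.5e6 - 1), 0.10)
  expect_lt(abs(f$params$k_off / 7.0 - 1), 0.10)
  expect_error(fit_kobs(ser$points[1:2, ], "bimolecular"), "at least")
  expect_error(fit_kobs(ser$points[1:4, ], "cooperative"), "at least")
})

test_that("mode comparison separates the mutant from the wild types", {
  expect_equal(compare_modes(simulate_fixture("alpha3dn", seed = 7))$selected,
               "bimolecular")
  expect_equal(compare_modes(simulate_fixture("human-20s", seed = 7))$selected,
               "cooperative")
  expect_equal(compare_modes(simulate_fixture("yeast-20s", seed = 7))$selected,
               "cooperative")
  # a 3-point series refuses selection but still reports the linear fit
  short <- simulate_fixture("alpha3dn", seed = 2)$points[c(1, 8, 15), ]
  cm <- compare_modes(short)
  expect_true(is.na(cm$selected))
  expect_s3_class(cm$fits$bimolecular, "kobs_fit")
})

test_that("site-number sweep ranks the generating n best", {
  sel <- vapply(1:8, function(s) {
    f <- fit_kobs(simulate_fixture("human-20s", seed = s), "cooperative",
                  n = 1:3)
    f$sweep$n[which.min(f$sweep$aicc)]
  }, integer(1))
  expect_gte(mean(sel == 3L), 0.9)
})

test_that("fit uncertainty is honest: identifiable parameters covered, ridge ones wide", {
  # On log-spaced 0.2-100 uM grids the transition region has K_o*x >> 1, so
  # the data pin k_o (terminal slope), k_off (intercept) and the compound
  # L*K_o^n (transition position), while K_o, K_c, L and k_c individually
  # sit on a likelihood ridge.  Intervals must cover the identifiable
  # parameters and be honestly wide along the ridge.
  res <- lapply(1:12, function(s) {
    f <- fit_kobs(simulate_fixture("human-20s", seed = s), "cooperative", n = 3)
    ci <- f$ci95
    covered <- function(nm, truth)
      is.na(ci$lower[ci$parameter == nm]) ||
        (truth >= ci$lower[ci$parameter == nm] &&
           truth <= ci$upper[ci$parameter == nm])
    ridge_width <- max(ci$upper[ci$parameter %in% c("K_o", "L")] /
                         pmax(ci$lower[ci$parameter %in% c("K_o", "L")],
                              .Machine$double.xmin))
    c(k_o = covered("k_o", 2.8e6), k_off = covered("k_off", 0.22),
      wide = !is.finite(ridge_width) || ridge_width > 100)
  })
  res <- do.call(rbind, res)
  expect_gte(mean(res[, "k_o"]), 0.9)
  expect_gte(mean(res[, "k_off"]), 0.9)
  expect_gte(mean(res[, "wide"]), 0.9)
})

test_that("parameter constructors validate their invariants", {
  expect_error(two_state_params(K_o = -1, k_o = 1e6, k_off = 1), "positive")
  expect_error(two_state_params(K_o = 1e7, K_c = 7e3, k_o = 1e6, k_off = 1),
               "all of K_c")
  expect_error(two_state_params(K_o = 1e7, k_o = 1e6, k_off = 1, n = 0),
               ">= 1")
  expect_true(is_bimolecular(fixture_params("alpha3dn")))
  expect_false(is_bimolecular(fixture_params("yeast-20s")))
})
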