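test_that("fixture registry carries the required reference sets", {
  expect_true(all(c("human-20s", "yeast-20s", "alpha3dn", "chtl-dose",
                    "sucllvy-inhibition", "stopped-flow", "toy-complex")
                  %in% fixtures()))
  expect_error(fixture("no-such-fixture"), "unknown fixture")
})

test_that("generation is deterministic: same name and seed, identical output", {
  for (nm in c("chtl-dose", "sucllvy-inhibition", "stopped-flow")) {
    a <- simulate_fixture(nm, seed = 42)
    b <- simulate_fixture(nm, seed = 42)
    expect_identical(a, b, label = nm)
  }
  # structure text is byte-identical
  expect_identical(unclass(simulate_fixture("toy-complex", seed = 7)),
                   unclass(simulate_fixture("toy-complex", seed = 7)))
  s1 <- simulate_fixture("human-20s", seed = 9)
  s2 <- simulate_fixture("human-20s", seed = 9)
  expect_identical(s1$points, s2$points)
  # and the generator does not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_fixture("chtl-dose", seed = 3))
  expect_identical(runif(1), before)
})

test_that("noiseless Michaelis grids reproduce the rate laws exactly", {
  p <- list(Vmax = 1, Km = 50, Ki = 2)
  d <- gen_michaelis("noncompetitive", p, s_grid = 50, i_grid = c(0, 2),
                     noise_cv = 0, seed = 1)
  expect_equal(d$v[d$I == 0], 0.5)   # S = Km, no inhibitor
  expect_equal(d$v[d$I == 2], 0.25)  # pure non-competitive halves at I = Ki
  expect_error(gen_michaelis("cooperative", p, 50, 0, 0, 1))
  expect_error(gen_michaelis("competitive", list(Vmax = -1, Km = 50, Ki = 2),
                             50, 0, 0, 1), "positive")
})

test_that("dose-response generator hits the half-activity point and limits", {
  d <- gen_dose_response(2, 1, c(1e-6, 2), noise_cv = 0, seed = 1)
  expect_equal(d$activity[2], 0.5)
  expect_equal(d$activity[1], 1, tolerance = 1e-5)
  expect_error(gen_dose_response(2, 1, numeric(0), 0, 1), "empty")
})

test_that("progress curves sum their phases at t = 0 and decay to the offset", {
  t <- c(0, seq(0.01, 10, length.out = 50))
  one <- gen_progress_curve(list(c(-0.05, 10)), 1, t, 0, 1)
  expect_equal(one$A[1], 0.95)
  expect_equal(one$A[length(t)], 1, tolerance = 1e-6)
  two <- gen_progress_curve(list(c(-0.05, 10), c(0.03, 1)), 1, t, 0, 1)
  expect_equal(two$A[1], 1 - 0.02)
  expect_error(
    gen_progress_curve(list(c(-0.05, 10), c(0.03, 10)), 1, t, 0, 1),
    "ill-conditioned")
  expect_error(gen_progress_curve(list(c(-0.05, 10)), 1, rev(t), 0, 1),
               "increasing")
})

test_that("noiseless k_obs series match direct arithmetic on the fixture constants", {
  ap <- fixture_params("alpha3dn")
  s <- gen_kobs_series(ap, 5e-6, noise_cv = 0, seed = 1)
  expect_equal(s$points$k_obs, 2.5e6 * 5e-6 + 7.0)   # 19.5 s^-1
  hp <- fixture_params("human-20s")
  sh <- gen_kobs_series(hp, c(1e-9, 5e-6), noise_cv = 0, seed = 1)
  expect_equal(sh$points$k_obs[1], 0.22, tolerance = 1e-3)  # intercept k_off
  expect_equal(sh$points$k_obs[2],
               oracle_kobs(5e-6, 1.8e7, 7e3, 2.8e6, 1.3e2, 0.22, 4e-6, 3),
               tolerance = 1e-12)
  expect_error(gen_kobs_series(hp, -1e-6, 0, 1), "> 0")
})

test_that("noiseless generation followed by the matching fit closes the loop", {
  # model-class closure at <= 1e-6 relative error
  hp <- fixture_params("human-20s")
  ser <- gen_kobs_series(hp, logspace(0.2e-6, 100e-6, 15), 0, 3)
  f <- fit_kobs(ser, "cooperative", n = 3)
  for (nm in c("K_o", "K_c", "k_o", "k_c", "k_off", "L"))
    expect_equal(f$params[[nm]], hp[[nm]], tolerance = 1e-6, label = nm)
  cv <- simulate_fixture("stopped-flow", seed = 3, noise_sd = 0)
  fe <- fit_exponentials(cv, 2)
  expect_equal(fe$phases$k_obs, c(10.4, 1.0), tolerance = 1e-6)
  expect_equal(fe$phases$amplitude, c(-0.05, 0.03), tolerance = 1e-6)
})

test_that("refits on noisy default fixtures recover truth within 10%", {
  d <- simulate_fixture("sucllvy-inhibition", seed = 4)
  f <- fit_inhibition(d, mechanisms = "noncompetitive")
  expect_lt(abs(f$fits$noncompetitive$params$Ki / 2 - 1), 0.10)
  dr <- simulate_fixture("chtl-dose", seed = 5)
  expect_lt(abs(fit_ic50(dr)$ic50 / 2 - 1), 0.10)
})

test_that("generated structures round-trip with conserved atom counts", {
  tc <- simulate_fixture("toy-complex", seed = 11)
  expect_equal(nrow(parse_structure(tc)$atoms), attr(tc, "n_atoms"))
  pr <- gen_pseudo_ring(4, 10, seed = 2)
  st <- parse_structure(pr)
  expect_equal(nrow(st$atoms), attr(pr, "n_atoms"))
  # >= 4 negative centroids even in the smallest ring
  expect_gte(length(attr(pr, "centroid_keys")), 4)
  expect_error(gen_pseudo_ring(3, 10), ">= 4")
  expect_error(gen_pseudo_ring(7, -1), "> 0")
})

test_that("datasets write to CSV with a provenance sidecar and read back", {
  d <- simulate_fixture("sucllvy-inhibition", seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d, path)
  back <- read_rate_grid_csv(path)
  expect_equal(back$v, d$v)
  prov <- readLines(paste0(path, ".provenance.txt"))
  expect_true(any(grepl("seed = 4", prov)))
  expect_true(any(grepl("truth.Ki = 2", prov, fixed = TRUE)))
  ser <- simulate_fixture("human-20s", seed = 2)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ser, path2)
  expect_equal(read_kobs_csv(path2)$k_obs, ser$points$k_obs)
  expect_error(read_kobs_csv(path), "lacks column")
})
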