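#' Simulate a substrate-by-inhibitor Michaelis-Menten rate grid
#'
#' Evaluates the chosen inhibition rate law (see [rate_law()]) on the full
#' `s_grid` x `i_grid` and applies multiplicative Gaussian noise,
#' `v = v_true * (1 + e)`, `e ~ N(0, noise_cv)`, matching the roughly
#' constant relative error of initial-rate measurements.  The generating
#' mechanism and true parameters are attached as provenance.
#'
#' @param mechanism One of `"competitive"`, `"uncompetitive"`, `"mixed"`,
#'   `"noncompetitive"`.
#' @param params List with `Vmax`, `Km` (uM), `Ki` (uM) and, for mixed,
#'   `alpha`.
#' @param s_grid,i_grid Substrate / inhibitor concentrations (uM); substrate
#'   must be > 0, inhibitor >= 0.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (>= 0).
#' @param seed Integer seed.
#' @return A `michaelis_dataset`: data frame `S`, `I`, `v` with attributes
#'   `mechanism`, `truth`, `seed`.
#' @export
gen_michaelis <- function(mechanism, params, s_grid, i_grid, noise_cv, seed) {
  mechanism <- match.arg(mechanism,
    c("competitive", "uncompetitive", "mixed", "noncompetitive"))
  for (nm in c("Vmax", "Km", "Ki"))
    if (is.null(params[[nm]]) || params[[nm]] <= 0)
      stop(sprintf("'%s' must be positive", nm), call. = FALSE)
  if (any(s_grid <= 0) || any(i_grid < 0))
    stop("substrate must be > 0 and inhibitor >= 0", call. = FALSE)
  if (noise_cv < 0) stop("'noise_cv' must be >= 0", call. = FALSE)
  grid <- expand.grid(S = s_grid, I = i_grid, KEEP.OUT.ATTRS = FALSE)
  v0 <- rate_law(mechanism, grid$S, grid$I, params)
  v <- with_seed(seed, v0 * (1 + stats::rnorm(length(v0), 0, noise_cv)))
  out <- data.frame(S = grid$S, I = grid$I, v = v)
  structure(out, class = c("michaelis_dataset", "data.frame"),
            mechanism = mechanism, truth = params,
            noise_cv = noise_cv, seed = seed)
}

#' Simulate a dose-response (fractional activity) series
#'
#' Fractional activity `a(I) = 1 / (1 + (I/ic50)^hill)`, with multiplicative
#' Gaussian noise as in [gen_michaelis()].
#'
#' @param ic50 Half-inhibition concentration (uM), > 0.
#' @param hill Hill slope, > 0.
#' @param i_grid Inhibitor concentrations (uM), non-empty.
#' @param noise_cv Relative noise level (>= 0).
#' @param seed Integer seed.
#' @return A `dose_response` data frame `I`, `activity` with attributes
#'   `truth` and `seed`.
#' @export
gen_dose_response <- function(ic50, hill, i_grid, noise_cv, seed) {
  if (ic50 <= 0 || hill <= 0) stop("ic50 and hill must be > 0", call. = FALSE)
  if (length(i_grid) == 0) stop("empty concentration grid", call. = FALSE)
  a0 <- 1 / (1 + (i_grid / ic50)^hill)
  a <- with_seed(seed, a0 * (1 + stats::rnorm(length(a0), 0, noise_cv)))
  structure(data.frame(I = i_grid, activity = a),
            class = c("dose_response", "data.frame"),
            truth = list(ic50 = ic50, hill = hill),
            noise_cv = noise_cv, seed = seed)
}

#' Simulate a stopped-flow absorbance progress curve
#'
#' Multi-exponential relaxation
#' `A(t) = offset + sum_i a_i exp(-k_i t)` plus additive Gaussian detector
#' noise.  Under the package's sign convention a negative amplitude is a
#' rising (hyperchromic) phase and a positive amplitude a falling
#' (hypochromic) one.
#'
#' @param phases List of `c(amplitude, rate)` pairs (AU, s^-1); rates > 0.
#' @param offset Final absorbance `A_inf` (AU).
#' @param t_grid Strictly increasing time grid (s).
#' @param noise_sd Additive noise standard deviation (AU), >= 0.
#' @param seed Integer seed.
#' @param wavelength_nm,porph_conc,enzyme_conc Optional metadata carried on
#'   the returned curve.
#' @return A `progress_curve` data frame `t`, `A` with attributes `truth`
#'   (phases, offset), `seed`, and the metadata fields.
#' @export
gen_progress_curve <- function(phases, offset, t_grid, noise_sd, seed,
                               wavelength_nm = NA_real_,
                               porph_conc = NA_real_,
                               enzyme_conc = NA_real_) {
  phases <- lapply(phases, function(ph) {
    ph <- unname(unlist(ph))
    if (length(ph) != 2 || ph[2] <= 0)
      stop("each phase is c(amplitude, rate) with rate > 0", call. = FALSE)
    ph
  })
  rates <- vapply(phases, `[`, numeric(1), 2)
  if (length(rates) > 1 && min(diff(sort(rates))) < 1e-9)
    stop("duplicate phase rates: ill-conditioned model", call. = FALSE)
  if (is.unsorted(t_grid, strictly = TRUE))
    stop("'t_grid' must be strictly increasing", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  A0 <- offset
  A <- rep(offset, length(t_grid))
  for (ph in phases) A <- A + ph[1] * exp(-ph[2] * t_grid)
  A <- with_seed(seed, A + stats::rnorm(length(A), 0, noise_sd))
  structure(data.frame(t = t_grid, A = A),
            class = c("progress_curve", "data.frame"),
            truth = list(phases = phases, offset = offset),
            noise_sd = noise_sd, seed = seed,
            wavelength_nm = wavelength_nm, porph_conc = porph_conc,
            enzyme_conc = enzyme_conc)
}

#' Simulate an observed-rate-constant series
#'
#' Evaluates [kobs_model()] (cooperative two-state law, or the linear
#' bimolecular law when `params` encodes it) on a concentration grid and
#' applies lognormal multiplicative noise with relative scale `noise_cv`,
#' keeping simulated rate constants positive.
#'
#' @param params A [two_state_params()] set (e.g. from [fixture_params()]).
#' @param x_grid Ligand concentrations (M), > 0.
#' @param noise_cv Relative noise level (>= 0).
#' @param seed Integer seed.
#' @return A `kobs_series` object: list with `points` (data frame `x`,
#'   `k_obs`), `truth`, `seed`, `label`.
#' @export
gen_kobs_series <- function(params, x_grid, noise_cv, seed) {
  stopifnot(inherits(params, "two_state_params"))
  if (any(x_grid <= 0)) stop("'x_grid' must be > 0", call. = FALSE)
  if (noise_cv < 0) stop("'noise_cv' must be >= 0", call. = FALSE)
  k0 <- kobs_model(x_grid, params)
  sdlog <- sqrt(log1p(noise_cv^2))   # lognormal with relative sd ~ noise_cv
  k <- with_seed(seed,
                 k0 * exp(stats::rnorm(length(k0), -sdlog^2 / 2, sdlog)))
  structure(list(points = data.frame(x = x_grid, k_obs = k),
                 truth = params, seed = seed, label = params$label),
            class = "kobs_series")
}

#' @export
print.kobs_series <- function(x, ...) {
  cat(sprintf("k_obs series (%s): %d concentrations, %.3g - %.3g M\n",
              x$label %||% "unlabelled", nrow(x$points),
              min(x$points$x), max(x$points$x)))
  invisible(x)
}

#' @export
as.data.frame.kobs_series <- function(x, ...) x$points
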