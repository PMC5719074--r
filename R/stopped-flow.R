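#' Multi-exponential decomposition of a progress curve
#'
#' Fits `A(t) = A_inf + sum_i a_i exp(-k_i t)` to an absorbance trace by
#' nonlinear least squares.  Rates are optimised on the log scale with the
#' amplitudes and offset profiled out by linear least squares (variable
#' projection), from a ladder of log-spaced multi-start rate seeds spanning
#' the observable window `1/t_max` to `10/t_min`; the best solution is then
#' refined with all parameters free to obtain the covariance.  Phases are
#' returned sorted by descending rate (temporal order).  Fits whose rates
#' come closer than a 1.05 ratio are flagged `degenerate`; phases whose
#' amplitude is within 2 standard errors of zero are flagged
#' `near_zero_amplitude`.
#'
#' Sign convention: the offset is the final absorbance, so a negative
#' amplitude is a phase in which absorbance rises towards the end value
#' (hyperchromic at the Soret band) and a positive amplitude a falling,
#' hypochromic phase.
#'
#' @param curve A `progress_curve` (data frame with `t`, `A`).
#' @param n Number of exponential phases (>= 1); the trace must have at
#'   least `5 * (2n + 1)` points.
#' @param n_starts Number of multi-start rate ladders (default 8).
#' @return An `exp_fit`: `n_phases`, `phases` (data frame `amplitude`,
#'   `k_obs`, `se_amplitude`, `se_k`, `sign_class`), `offset`, `ssr`,
#'   `aicc`, `degenerate`, `near_zero_amplitude`, `fitted`.
#' @export
fit_exponentials <- function(curve, n, n_starts = 8L) {
  df <- as.data.frame(curve)
  stopifnot(all(c("t", "A") %in% names(df)))
  n <- as.integer(n)
  if (n < 1) stop("'n' must be >= 1", call. = FALSE)
  if (nrow(df) < 5 * (2 * n + 1))
    stop(sprintf("need at least %d points for %d phases", 5 * (2 * n + 1), n),
         call. = FALSE)
  t <- df$t; A <- df$A

  # variable projection: given log-rates, solve offset+amplitudes linearly
  varpro_ssr <- function(logk) {
    X <- cbind(1, exp(-t %o% exp(logk)))
    fit <- stats::lm.fit(X, A)
    sum(fit$residuals^2)
  }
  k_lo <- 1 / max(t); k_hi <- 10 / min(t[t > 0])
  anchors <- logspace(k_lo, k_hi, n_starts + n - 1)
  starts <- lapply(seq_len(n_starts), function(i) log(anchors[i:(i + n - 1)]))

  best <- NULL
  for (s in starts) {
    opt <- tryCatch(
      if (n == 1L) {
        stats::optim(s, varpro_ssr, method = "Brent",
                     lower = log(k_lo) - 3, upper = log(k_hi) + 3,
                     control = list(reltol = 1e-12))
      } else {
        stats::optim(s, varpro_ssr, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-12))
      },
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("exponential fit failed to converge", call. = FALSE)

  # full refinement for the covariance matrix
  logk <- best$par
  X <- cbind(1, exp(-t %o% exp(logk)))
  lin <- stats::lm.fit(X, A)$coefficients
  theta0 <- c(lin[1], lin[-1], logk)   # offset, amplitudes, log-rates
  resid_fn <- function(theta) {
    off <- theta[1]; a <- theta[2:(n + 1)]; k <- exp(theta[(n + 2):(2 * n + 1)])
    off + colSums(a * t(exp(-t %o% k))) - A
  }
  fit <- minpack.lm::nls.lm(par = theta0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 400))
  theta <- fit$par
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(theta)))
  offset <- unname(theta[1])
  amp <- unname(theta[2:(n + 1)])
  rate <- unname(exp(theta[(n + 2):(2 * n + 1)]))
  se_amp <- unname(se[2:(n + 1)])
  se_rate <- rate * unname(se[(n + 2):(2 * n + 1)])  # delta method, log scale

  ord <- order(rate, decreasing = TRUE)
  phases <- data.frame(
    amplitude = amp[ord], k_obs = rate[ord],
    se_amplitude = se_amp[ord], se_k = se_rate[ord],
    sign_class = ifelse(amp[ord] < 0, "hyperchromic", "hypochromic"),
    row.names = NULL)
  degenerate <- n > 1 && any(phases$k_obs[-n] / phases$k_obs[-1] < 1.05)
  near_zero <- !is.na(phases$se_amplitude) &
    abs(phases$amplitude) < 2 * phases$se_amplitude
  ssr <- fit$deviance
  structure(list(
    n_phases = n, phases = phases, offset = offset, ssr = ssr,
    aicc = aicc_from_ssr(ssr, length(t), 2 * n + 1),
    degenerate = degenerate, near_zero_amplitude = near_zero,
    fitted = A + resid_fn(theta), data = df,
    converged = fit$info %in% 1:4),
    class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("%d-phase exponential fit: offset %.4g AU, SSR %.3g, AICc %.1f%s\n",
              x$n_phases, x$offset, x$ssr, x$aicc,
              if (x$degenerate) " [degenerate rates]" else ""))
  print(x$phases, row.names = FALSE)
  invisible(x)
}

#' Select the number of exponential phases
#'
#' Fits `n = 1 .. max_n` phases with [fit_exponentials()] and selects by
#' AICc.  Candidates are excluded from selection when the fit failed, when
#' its rates are degenerate (ratio below 1.05), or when any amplitude is
#' within 2 standard errors of zero - the last rule prevents AICc from
#' dressing noise as an extra phase.
#'
#' @param curve A `progress_curve`.
#' @param max_n Largest phase count to try (>= 1).
#' @return A `phase_selection`: `selected` (integer), `fits` (per-n
#'   `exp_fit` or `NULL`), `table` (n, aicc, eligible, reason).
#' @export
select_n_phases <- function(curve, max_n = 3L) {
  max_n <- as.integer(max_n)
  if (max_n < 1) stop("'max_n' must be >= 1", call. = FALSE)
  fits <- vector("list", max_n)
  rows <- list()
  for (n in seq_len(max_n)) {
    fit <- tryCatch(fit_exponentials(curve, n), error = function(e) NULL)
    fits[[n]] <- fit
    reason <- if (is.null(fit)) {
      "fit failed"
    } else if (fit$degenerate) {
      "degenerate rates"
    } else if (n > 1 && any(fit$near_zero_amplitude)) {
      "amplitude < 2 SE"
    } else ""
    rows[[n]] <- data.frame(
      n = n, aicc = if (is.null(fit)) NA_real_ else fit$aicc,
      eligible = reason == "", reason = reason)
  }
  tab <- do.call(rbind, rows)
  eligible <- which(tab$eligible)
  selected <- if (length(eligible)) {
    eligible[which.min(tab$aicc[eligible])]
  } else 1L
  structure(list(selected = as.integer(selected), fits = fits, table = tab),
            class = "phase_selection")
}

#' @export
print.phase_selection <- function(x, ...) {
  cat(sprintf("Selected %d phase(s)\n", x$selected))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Temporal sign sequence of fitted phases
#'
#' Orders the phases of an [fit_exponentials()] result by descending rate
#' (fastest event first) and returns their chromic character: a phase whose
#' amplitude is negative raises the absorbance towards the final value and
#' is labelled `"hyperchromic"`; a positive amplitude is `"hypochromic"`.
#'
#' @param fit An `exp_fit`.
#' @return Character vector of `"hyperchromic"` / `"hypochromic"` labels in
#'   temporal order.
#' @export
classify_phases <- function(fit) {
  stopifnot(inherits(fit, "exp_fit"))
  fit$phases$sign_class   # phases already sorted by descending k_obs
}

#' Collect per-phase k_obs series across ligand concentrations
#'
#' Combines exponential fits of traces recorded at different ligand
#' concentrations into per-phase `(x, k_obs, se)` tables.  Phases are
#' matched across concentrations by rate rank (fastest with fastest), not
#' by amplitude.  Curves with more phases than the modal count have their
#' extra phases excluded with a warning; curves with fewer contribute to the
#' phases they have.
#'
#' @param fits List of `exp_fit` objects.
#' @param concentrations Ligand concentration (M) for each fit.
#' @return List of `kobs_series`-like data frames, one per phase rank, each
#'   with columns `x`, `k_obs`, `se`, ordered by `x`.
#' @export
collect_kobs <- function(fits, concentrations) {
  stopifnot(length(fits) == length(concentrations))
  counts <- vapply(fits, `[[`, integer(1), "n_phases")
  n_modal <- as.integer(names(which.max(table(counts))))
  if (any(counts != n_modal))
    warning(sprintf(
      "phase-count mismatch across concentrations (modal %d); extra phases excluded",
      n_modal))
  series <- lapply(seq_len(n_modal), function(rank) {
    rows <- do.call(rbind, lapply(seq_along(fits), function(i) {
      ph <- fits[[i]]$phases
      if (rank > nrow(ph)) return(NULL)
      data.frame(x = concentrations[i], k_obs = ph$k_obs[rank],
                 se = ph$se_k[rank])
    }))
    rows[order(rows$x), , drop = FALSE]
  })
  names(series) <- paste0("phase", seq_len(n_modal))
  series
}
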