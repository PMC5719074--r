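#' Inhibition rate laws
#'
#' Initial-rate laws for reversible inhibition of a Michaelis-Menten enzyme:
#' \itemize{
#'   \item competitive:    `v = Vmax S / (Km (1 + I/Ki) + S)`
#'   \item uncompetitive:  `v = Vmax S / (Km + S (1 + I/Ki))`
#'   \item mixed:          `v = Vmax S / (Km (1 + I/Ki) + S (1 + I/(alpha Ki)))`
#'   \item non-competitive: mixed with `alpha = 1` (Vmax falls, Km unchanged)
#' }
#'
#' @param mechanism One of `"competitive"`, `"uncompetitive"`, `"mixed"`,
#'   `"noncompetitive"`.
#' @param S Substrate concentration(s), uM (>= 0; returns 0 at S = 0).
#' @param I Inhibitor concentration(s), uM (>= 0).
#' @param params List with positive `Vmax`, `Km`, `Ki` and, for mixed,
#'   `alpha`.
#' @return Rate(s), same units as `Vmax`.
#' @export
rate_law <- function(mechanism, S, I, params) {
  mechanism <- match.arg(mechanism,
    c("competitive", "uncompetitive", "mixed", "noncompetitive"))
  Vmax <- params$Vmax; Km <- params$Km; Ki <- params$Ki
  if (any(c(Vmax, Km, Ki) <= 0)) stop("Vmax, Km, Ki must be > 0", call. = FALSE)
  alpha <- switch(mechanism,
                  mixed = {
                    if (is.null(params$alpha) || params$alpha <= 0)
                      stop("mixed mechanism needs positive 'alpha'", call. = FALSE)
                    params$alpha
                  },
                  noncompetitive = 1,
                  NA_real_)
  denom <- switch(mechanism,
    competitive = Km * (1 + I / Ki) + S,
    uncompetitive = Km + S * (1 + I / Ki),
    Km * (1 + I / Ki) + S * (1 + I / (alpha * Ki)))
  ifelse(S <= 0, 0, Vmax * S / denom)
}

ss_check_data <- function(data) {
  data <- as.data.frame(data)
  if (!all(c("S", "I", "v") %in% names(data)))
    stop("data needs columns 'S', 'I', 'v'", call. = FALSE)
  if (any(data$S <= 0) || any(data$v < 0))
    stop("need S > 0 and v >= 0", call. = FALSE)
  data
}

ss_param_count <- c(competitive = 3L, uncompetitive = 3L,
                    noncompetitive = 3L, mixed = 4L)

# Relative residuals: multiplicative rate noise makes the error roughly
# proportional to the rate, so weight each residual by 1/v_obs.
ss_resid <- function(theta, mechanism, data) {
  p <- as.list(exp(theta))
  names(p) <- names(theta)
  v_mod <- rate_law(mechanism, data$S, data$I, p)
  (v_mod - data$v) / pmax(data$v, 1e-12)
}

#' Fit inhibition mechanisms to a substrate-by-inhibitor rate grid
#'
#' Globally fits each candidate rate law (see [rate_law()]) across all
#' inhibitor levels simultaneously by weighted nonlinear least squares on
#' untransformed rates (residuals weighted `1/v`, matching multiplicative
#' rate noise), with multi-start initialisation: `Km`/`Vmax` seeded from the
#' uninhibited curve and `Ki` from a log-spaced ladder.  Mechanisms are
#' compared by AICc; an extra-sum-of-squares F-test of mixed against each
#' nested 3-parameter law is reported as a secondary criterion.
#'
#' @param data Data frame with columns `S` (uM), `I` (uM), `v`, e.g. from
#'   [gen_michaelis()].  Needs >= 2 distinct S and >= 2 distinct I.
#' @param mechanisms Candidate mechanisms (default all four).
#' @param ki_starts Number of log-spaced `Ki` starting values in
#'   0.1-100 uM (default 8).
#' @return An `inhibition_fit` object: `fits` (per-mechanism list with
#'   `params`, `se`, `ssr`, `aicc`, `converged`, `residuals`), `selected`
#'   (AICc-best mechanism), `aicc_table`, `f_tests`.
#' @export
fit_inhibition <- function(data,
                           mechanisms = c("competitive", "uncompetitive",
                                          "noncompetitive", "mixed"),
                           ki_starts = 8L) {
  data <- ss_check_data(data)
  if (length(unique(data$S)) < 2 || length(unique(data$I)) < 2)
    stop("mechanism fitting needs >= 2 distinct S and >= 2 distinct I",
         call. = FALSE)
  mechanisms <- match.arg(mechanisms, several.ok = TRUE)

  # starting Vmax/Km from the least-inhibited rows (I minimum)
  base <- data[data$I == min(data$I), ]
  Vmax0 <- max(base$v) * 1.2
  half <- Vmax0 / 2
  Km0 <- base$S[which.min(abs(base$v - half))]
  if (Km0 <= 0 || !is.finite(Km0)) Km0 <- stats::median(data$S)
  ki_grid <- logspace(0.1, 100, ki_starts)

  fits <- lapply(mechanisms, function(mech) {
    best <- NULL
    for (Ki0 in ki_grid) {
      start <- log(c(Vmax = Vmax0, Km = Km0, Ki = Ki0))
      if (mech == "mixed") start <- c(start, log(c(alpha = 1)))
      fit <- tryCatch(
        minpack.lm::nls.lm(par = start, fn = ss_resid, mechanism = mech,
                           data = data,
                           control = minpack.lm::nls.lm.control(maxiter = 300)),
        error = function(e) NULL)
      if (is.null(fit)) next
      if (is.null(best) || fit$deviance < best$deviance) best <- fit
    }
    if (is.null(best))
      return(list(mechanism = mech, converged = FALSE, ssr = Inf, aicc = Inf))
    est <- exp(best$par)
    se <- tryCatch(summary(best)$coefficients[, "Std. Error"],
                   error = function(e) rep(NA_real_, length(best$par)))
    list(mechanism = mech, params = as.list(est), se_log = se,
         ssr = best$deviance,
         aicc = aicc_from_ssr(best$deviance, nrow(data),
                              ss_param_count[[mech]]),
         converged = best$info %in% 1:4,
         residuals = ss_resid(best$par, mech, data))
  })
  names(fits) <- mechanisms

  aicc_table <- data.frame(
    mechanism = mechanisms,
    ssr = vapply(fits, `[[`, numeric(1), "ssr"),
    aicc = vapply(fits, `[[`, numeric(1), "aicc"),
    row.names = NULL)
  aicc_table$delta_aicc <- aicc_table$aicc - min(aicc_table$aicc)
  selected <- mechanisms[which.min(aicc_table$aicc)]

  f_tests <- NULL
  if ("mixed" %in% mechanisms) {
    nested <- setdiff(mechanisms, "mixed")
    f_tests <- do.call(rbind, lapply(nested, function(mech) {
      df1 <- 1L; df2 <- nrow(data) - 4L
      if (df2 <= 0 || !is.finite(fits[[mech]]$ssr)) return(NULL)
      fstat <- ((fits[[mech]]$ssr - fits$mixed$ssr) / df1) /
        (fits$mixed$ssr / df2)
      data.frame(nested = mech, F = fstat, df1 = df1, df2 = df2,
                 p_value = stats::pf(fstat, df1, df2, lower.tail = FALSE))
    }))
    # The fourth parameter must earn its keep: when mixed wins on AICc but
    # some nested 3-parameter law is not rejected by the extra-sum-of-squares
    # F-test (alpha = 0.01), report the parsimonious law (AICc-best among
    # the non-rejected ones).
    if (selected == "mixed" && !is.null(f_tests)) {
      keep <- f_tests$nested[f_tests$p_value > 0.01]
      if (length(keep)) {
        sub <- aicc_table[aicc_table$mechanism %in% keep, ]
        selected <- sub$mechanism[which.min(sub$aicc)]
      }
    }
  }
  structure(list(fits = fits, selected = selected, aicc_table = aicc_table,
                 f_tests = f_tests, data = data),
            class = "inhibition_fit")
}

#' @export
print.inhibition_fit <- function(x, ...) {
  cat(sprintf("Inhibition mechanism fit on %d rates; selected: %s\n",
              nrow(x$data), x$selected))
  print(x$aicc_table, row.names = FALSE)
  sel <- x$fits[[x$selected]]
  cat("selected-model parameters:\n")
  print(unlist(sel$params))
  invisible(x)
}

#' Fit an IC50 dose-response curve
#'
#' Fits fractional activity `a = 1 / (1 + (I/IC50)^h)` by nonlinear least
#' squares in log-parameter space; the Hill slope is fixed at 1 unless
#' `hill_free = TRUE`.
#'
#' @param data Data frame with columns `I` (uM) and `activity`, e.g. from
#'   [gen_dose_response()].  Needs >= 4 points spanning the transition
#'   (not all activities above 0.8 or below 0.2).
#' @param hill_free Fit the Hill slope (default fixed at 1).
#' @return A `dose_response_fit`: `ic50`, `hill`, `se_log`, `ssr`, `aicc`,
#'   `fitted`.
#' @export
fit_ic50 <- function(data, hill_free = FALSE) {
  data <- as.data.frame(data)
  if (!all(c("I", "activity") %in% names(data)))
    stop("data needs columns 'I' and 'activity'", call. = FALSE)
  if (nrow(data) < 4) stop("need >= 4 dose-response points", call. = FALSE)
  if (all(data$activity > 0.8) || all(data$activity < 0.2))
    stop("no inhibition transition in the data; cannot place an IC50",
         call. = FALSE)
  resid_fn <- function(theta) {
    ic50 <- exp(theta[1])
    h <- if (hill_free) exp(theta[2]) else 1
    1 / (1 + (data$I / ic50)^h) - data$activity
  }
  ic50_0 <- data$I[which.min(abs(data$activity - 0.5))]
  if (ic50_0 <= 0) ic50_0 <- stats::median(data$I[data$I > 0])
  start <- log(c(ic50 = ic50_0))
  if (hill_free) start <- c(start, log(c(hill = 1)))
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(start)))
  k <- length(start)
  structure(list(ic50 = exp(fit$par[[1]]),
                 hill = if (hill_free) exp(fit$par[[2]]) else 1,
                 hill_free = hill_free, se_log = se, ssr = fit$deviance,
                 aicc = aicc_from_ssr(fit$deviance, nrow(data), k),
                 fitted = data$activity + resid_fn(fit$par),
                 data = data),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("IC50 = %.3g uM (hill %s %.3g), %d points, SSR = %.3g\n",
              x$ic50, if (x$hill_free) "=" else "fixed at", x$hill,
              nrow(x$data), x$ssr))
  invisible(x)
}

#' Lineweaver-Burk double-reciprocal diagnostics
#'
#' Transforms the rate grid to `(1/S, 1/v)`, fits an ordinary least-squares
#' line per inhibitor level, computes all pairwise line intersections, and
#' reports a classification hint from where the lines meet: a common
#' y-intercept (at `1/Vmax`) indicates competitive inhibition, a common
#' x-intercept (at `-1/Km`) pure non-competitive, and parallel lines
#' uncompetitive.  Retained as a diagnostic/plot companion; mechanism
#' selection itself is done on untransformed rates by [fit_inhibition()].
#'
#' @param data Data frame with columns `S`, `I`, `v`.  Rows with `v = 0`
#'   are excluded with a warning (the reciprocal is undefined).
#' @param rel_tol Relative spread below which intercepts/slopes are deemed
#'   shared (default 0.05).
#' @return A `lineweaver_burk` object: `lines` (per-I slope/intercept),
#'   `points` (transformed data), `intersections` (pairwise), `hint`.
#' @export
lineweaver_burk <- function(data, rel_tol = 0.05) {
  data <- ss_check_data(data)
  if (any(data$v == 0)) {
    warning("excluding v = 0 points from the reciprocal transform")
    data <- data[data$v > 0, ]
  }
  pts <- data.frame(I = data$I, inv_S = 1 / data$S, inv_v = 1 / data$v)
  lines <- do.call(rbind, lapply(split(pts, pts$I), function(d) {
    co <- stats::coef(stats::lm(inv_v ~ inv_S, data = d))
    data.frame(I = d$I[1], intercept = co[[1]], slope = co[[2]])
  }))
  rownames(lines) <- NULL
  combs <- if (nrow(lines) >= 2) utils::combn(nrow(lines), 2) else NULL
  intersections <- if (!is.null(combs)) {
    do.call(rbind, lapply(seq_len(ncol(combs)), function(j) {
      a <- lines[combs[1, j], ]; b <- lines[combs[2, j], ]
      dm <- a$slope - b$slope
      x <- if (abs(dm) < 1e-12) NA_real_ else (b$intercept - a$intercept) / dm
      data.frame(I1 = a$I, I2 = b$I, x = x,
                 y = if (is.na(x)) NA_real_ else a$intercept + a$slope * x)
    }))
  } else NULL
  rel_spread <- function(z) {
    m <- mean(abs(z)); if (m == 0) 0 else (max(z) - min(z)) / m
  }
  hint <- if (rel_spread(lines$slope) < rel_tol) {
    "uncompetitive"
  } else if (rel_spread(lines$intercept) < rel_tol) {
    "competitive"
  } else if (rel_spread(-lines$intercept / lines$slope) < rel_tol) {
    "noncompetitive"
  } else "mixed"
  structure(list(lines = lines, points = pts, intersections = intersections,
                 hint = hint),
            class = "lineweaver_burk")
}

#' @export
print.lineweaver_burk <- function(x, ...) {
  cat(sprintf("Lineweaver-Burk diagnostics: %d inhibitor levels, hint: %s\n",
              nrow(x$lines), x$hint))
  print(x$lines, row.names = FALSE)
  invisible(x)
}
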