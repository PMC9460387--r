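#' Convert a TG step into a conversion series
#'
#' For one decomposition step on `[T_lo, T_hi]`, the conversion at temperature
#' T is \eqn{\alpha(T) = (w_0 - w(T)) / (w_0 - w_f)} with \eqn{w_0, w_f} the
#' masses at the step boundaries. The series also carries the mass loss at
#' completion \eqn{w_c = w_0 - w_f}, the residual mass loss
#' \eqn{w_r = w_c - (w_0 - w) = w - w_f}, the smoothed mass-loss rate `dw_dt`
#' and \eqn{d\alpha/dT = -(dw/dt)/(\beta w_c)} restricted to the step.
#'
#' @param curve A [tga_curve()].
#' @param step Numeric length-2: the step's temperature interval (K), e.g. one
#'   row of [segment_steps()].
#' @param dtg Optional precomputed [compute_dtg()] series; computed with
#'   default smoothing when omitted.
#' @return A data.frame of class `conversion_series` with columns
#'   `temperature`, `alpha`, `dalpha_dT`, `dw_dt`, `w_r`, and attributes
#'   `beta` (K/min) and `w_c` (mg). Edge-affected derivative points are
#'   dropped.
#' @export
compute_conversion <- function(curve, step, dtg = NULL) {
  stopifnot(inherits(curve, "tga_curve"))
  if (length(step) < 2) ck_stop("step must give a temperature interval", "ck_invalid_step_interval")
  T_lo <- min(step[[1]], step[[2]]); T_hi <- max(step[[1]], step[[2]])
  Tv <- curve$temperature
  if (T_lo < min(Tv) - 1e-9 || T_hi > max(Tv) + 1e-9)
    ck_stop("step interval outside the curve's temperature range", "ck_invalid_step_interval")
  if (is.null(dtg)) dtg <- compute_dtg(curve)

  idx <- which(Tv >= T_lo & Tv <= T_hi)
  if (length(idx) < 10) ck_stop("too few points inside the step interval", "ck_too_few_points")
  w0 <- curve$mass[idx[1]]
  wf <- curve$mass[idx[length(idx)]]
  w_c <- w0 - wf
  if (w_c <= 0) ck_stop("no mass loss across the step", "ck_zero_mass_loss")

  alpha <- (w0 - curve$mass[idx]) / w_c
  structure(
    data.frame(
      temperature = Tv[idx],
      alpha = alpha,
      dalpha_dT = -dtg$dw_dt[idx] / (curve$beta * w_c),
      dw_dt = dtg$dw_dt[idx],
      w_r = curve$mass[idx] - wf
    ),
    class = c("conversion_series", "data.frame"),
    beta = curve$beta, w_c = w_c
  )
}

# Shared plumbing -------------------------------------------------------

conv_window <- function(conv, alpha_window) {
  lo <- alpha_window[1]; hi <- alpha_window[2]
  if (!(lo >= 0 && hi <= 1 && lo < hi))
    ck_stop("alpha_window must satisfy 0 <= lo < hi <= 1", "ck_invalid_window")
  conv[is.finite(conv$dalpha_dT) & conv$alpha >= lo & conv$alpha <= hi, , drop = FALSE]
}

ols_fit <- function(x, y) {
  fit <- stats::lm(y ~ x)
  ssr <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = if (sst > 0) max(0, 1 - ssr / sst) else 0)
}

# `points` holds the transformed (x, y) pairs the line was fitted to -- the
# per-method linearization panel a practitioner would plot as a diagnostic.
kinetic_fit <- function(method, E, n, A, slope, intercept, r_squared,
                        alpha_window, n_points_used, points = NULL) {
  structure(
    list(method = method, E = E, n = n, A = A, slope = slope,
         intercept = intercept, r_squared = r_squared,
         alpha_window = alpha_window, n_points_used = n_points_used,
         points = points),
    class = "kinetic_fit"
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit:%s> E = %.2f kJ/mol | n = %s | A = %s /min | R^2 = %.5f | %d pts\n",
              x$method, x$E,
              if (is.na(x$n)) "-" else format(x$n),
              if (is.na(x$A)) "-" else format(x$A, digits = 3),
              x$r_squared, x$n_points_used))
  invisible(x)
}

#' Freeman-Carroll difference-differential kinetic fit
#'
#' The Freeman-Carroll method removes the pre-exponential factor by pairwise
#' differencing. For successive usable points,
#' \deqn{\frac{\Delta \log_{10} (dw/dt)}{\Delta \log_{10} w_r}
#'   = -\frac{E_a}{2.303 R} \cdot
#'     \frac{\Delta (1/T)}{\Delta \log_{10} w_r} + n,}
#' so an ordinary least-squares line through the transformed pairs has slope
#' \eqn{-E_a/(2.303 R)} and intercept equal to the reaction order n. Pairs
#' with \eqn{|\Delta \log_{10} w_r|} below `min_dlogwr` are discarded to avoid
#' amplifying discretization error. The pre-exponential factor is not
#' identified by this method.
#'
#' @param conv A [compute_conversion()] series.
#' @param alpha_window Conversion window used for fitting, default
#'   `c(0.05, 0.95)`; baseline and tail points outside it are ignored.
#' @param min_dlogwr Minimum \eqn{|\Delta \log_{10} w_r|} for a usable pair.
#' @return A `kinetic_fit` with `E` (kJ/mol) and `n`; `A` is `NA`.
#' @references Freeman, E. S., Carroll, B. (1958) J. Phys. Chem. 62, 394-397.
#' @export
freeman_carroll <- function(conv, alpha_window = c(0.05, 0.95), min_dlogwr = 0.005) {
  d <- conv_window(conv, alpha_window)
  d <- d[d$w_r > 0 & d$dw_dt < 0, , drop = FALSE]
  if (nrow(d) < 9) ck_stop("too few usable points for Freeman-Carroll", "ck_too_few_points")
  lrate <- log10(-d$dw_dt)
  lwr <- log10(d$w_r)
  invT <- 1 / d$temperature
  # successive usable pairs: walk forward from the last accepted anchor and
  # accept a pair only once |dlog10 w_r| clears the floor, so no difference
  # ever divides by a near-zero increment
  anchor <- 1L
  ai <- integer(0); bi <- integer(0)
  for (i in 2:nrow(d)) {
    if (abs(lwr[i] - lwr[anchor]) >= min_dlogwr) {
      ai <- c(ai, anchor); bi <- c(bi, i)
      anchor <- i
    }
  }
  if (length(ai) < 8)
    ck_stop("too few point pairs after the |dlog10 w_r| filter", "ck_degenerate_fit")
  dlwr <- lwr[bi] - lwr[ai]
  Y <- (lrate[bi] - lrate[ai]) / dlwr
  X <- (invT[bi] - invT[ai]) / dlwr
  f <- ols_fit(X, Y)
  if (abs(f$slope) < 1e-12) ck_stop("degenerate Freeman-Carroll fit (|slope| ~ 0)", "ck_degenerate_fit")
  E <- -f$slope * 2.303 * R_GAS / 1000
  kinetic_fit("freeman_carroll", E = E, n = f$intercept, A = NA_real_,
              slope = f$slope, intercept = f$intercept, r_squared = f$r_squared,
              alpha_window = alpha_window, n_points_used = length(ai),
              points = data.frame(x = X, y = Y))
}

#' Sharp-Wentworth first-order kinetic fit
#'
#' Assumes first-order kinetics (n = 1) and linearizes the rate law as
#' \deqn{\log_{10}\frac{dc/dT}{1-c} = \log_{10}\frac{A}{\beta}
#'   - \frac{E_a}{2.303\,R\,T},}
#' with c the conversion and \eqn{\beta} the linear heating rate. Least
#' squares against 1/T gives \eqn{E_a} from the slope and A from the
#' intercept; a high R^2 supports the assumed first order.
#'
#' @inheritParams freeman_carroll
#' @return A `kinetic_fit` with `E` (kJ/mol), `A` (1/min) and `n = 1`.
#' @references Sharp, J. H., Wentworth, S. A. (1969) Anal. Chem. 41, 2060-2062.
#' @export
sharp_wentworth <- function(conv, alpha_window = c(0.05, 0.95)) {
  d <- conv_window(conv, alpha_window)
  d <- d[d$alpha < 1 & d$alpha > 0 & d$dalpha_dT > 0, , drop = FALSE]
  if (nrow(d) < 8) ck_stop("too few usable points for Sharp-Wentworth", "ck_too_few_points")
  y <- log10(d$dalpha_dT / (1 - d$alpha))
  x <- 1 / d$temperature
  f <- ols_fit(x, y)
  beta <- attr(conv, "beta")
  E <- -f$slope * 2.303 * R_GAS / 1000
  A <- beta * 10^f$intercept
  kinetic_fit("sharp_wentworth", E = E, n = 1, A = A,
              slope = f$slope, intercept = f$intercept, r_squared = f$r_squared,
              alpha_window = alpha_window, n_points_used = nrow(d),
              points = data.frame(x = x, y = y))
}

#' Achar differential model-fitting kinetic estimate
#'
#' Differential model fitting over a grid of candidate reaction orders: for
#' each n, least squares of
#' \deqn{\ln\frac{\beta \, d\alpha/dT}{(1-\alpha)^n} = \ln A - \frac{E_a}{R\,T}}
#' against 1/T; the order maximizing R^2 is selected (ties broken toward the
#' smallest n). Slope gives \eqn{-E_a/R}, intercept \eqn{\ln A}.
#'
#' @inheritParams freeman_carroll
#' @param n_grid Candidate reaction orders. Default `seq(0.25, 3, by = 0.05)`.
#' @return A `kinetic_fit` with the selected `n`, `E` (kJ/mol), `A` (1/min).
#' @export
achar <- function(conv, n_grid = seq(0.25, 3, by = 0.05),
                  alpha_window = c(0.05, 0.95)) {
  if (!length(n_grid)) ck_stop("n_grid must be non-empty", "ck_invalid_grid")
  d <- conv_window(conv, alpha_window)
  d <- d[d$alpha < 1 & d$dalpha_dT > 0, , drop = FALSE]
  if (nrow(d) < 8) ck_stop("too few usable points for Achar", "ck_too_few_points")
  beta <- attr(conv, "beta")
  x <- 1 / d$temperature
  best <- NULL
  for (n in sort(n_grid)) {
    fn <- (1 - d$alpha)^n
    ok <- fn > 0 & is.finite(fn)
    if (sum(ok) < 8) next
    y <- log(beta * d$dalpha_dT[ok] / fn[ok])
    f <- ols_fit(x[ok], y)
    if (is.null(best) || f$r_squared > best$r_squared + 1e-12) {
      best <- c(f, list(n = n, m = sum(ok), points = data.frame(x = x[ok], y = y)))
    }
  }
  if (is.null(best)) ck_stop("all points excluded on every candidate order", "ck_degenerate_fit")
  kinetic_fit("achar", E = -best$slope * R_GAS / 1000, n = best$n,
              A = exp(best$intercept), slope = best$slope,
              intercept = best$intercept, r_squared = best$r_squared,
              alpha_window = alpha_window, n_points_used = best$m,
              points = best$points)
}

# Integral kinetic model g(alpha) for reaction order n.
g_alpha <- function(alpha, n) {
  if (abs(n - 1) < 1e-12) -log(1 - alpha)
  else (1 - (1 - alpha)^(1 - n)) / (1 - n)
}

#' Coats-Redfern integral model-fitting kinetic estimate
#'
#' Integral model fitting: with \eqn{g(\alpha) = [1-(1-\alpha)^{1-n}]/(1-n)}
#' (and \eqn{-\ln(1-\alpha)} at n = 1), the Coats-Redfern approximation gives
#' \deqn{\ln\frac{g(\alpha)}{T^2} = \ln\frac{A\,R}{\beta\,E_a} - \frac{E_a}{R\,T}}
#' (the small 1 - 2RT/E correction neglected). For each candidate order a
#' least-squares line against 1/T is fitted; the order maximizing R^2 is
#' selected (ties toward smallest n), E comes from the slope and A from the
#' intercept.
#'
#' @inheritParams achar
#' @return A `kinetic_fit` with the selected `n`, `E` (kJ/mol), `A` (1/min).
#' @references Coats, A. W., Redfern, J. P. (1964) Nature 201, 68-69.
#' @export
coats_redfern <- function(conv, n_grid = seq(0.25, 3, by = 0.05),
                          alpha_window = c(0.05, 0.95)) {
  if (!length(n_grid)) ck_stop("n_grid must be non-empty", "ck_invalid_grid")
  d <- conv_window(conv, alpha_window)
  d <- d[d$alpha > 0 & d$alpha < 1, , drop = FALSE]
  if (nrow(d) < 8) ck_stop("too few usable points for Coats-Redfern", "ck_too_few_points")
  beta <- attr(conv, "beta")
  x <- 1 / d$temperature
  best <- NULL
  for (n in sort(n_grid)) {
    g <- g_alpha(d$alpha, n)
    ok <- is.finite(g) & g > 0
    if (sum(ok) < 8) next
    y <- log(g[ok] / d$temperature[ok]^2)
    f <- ols_fit(x[ok], y)
    if (is.null(best) || f$r_squared > best$r_squared + 1e-12) {
      best <- c(f, list(n = n, m = sum(ok), points = data.frame(x = x[ok], y = y)))
    }
  }
  if (is.null(best)) ck_stop("all points excluded on every candidate order", "ck_degenerate_fit")
  E_J <- -best$slope * R_GAS            # J/mol
  A <- exp(best$intercept) * beta * E_J / R_GAS
  kinetic_fit("coats_redfern", E = E_J / 1000, n = best$n, A = A,
              slope = best$slope, intercept = best$intercept,
              r_squared = best$r_squared, alpha_window = alpha_window,
              n_points_used = best$m, points = best$points)
}

#' Cross-method consensus on the activation energy
#'
#' Independent model-fitting estimators agreeing on the activation energy of
#' the same decomposition step is the standard reliability check. The
#' relative spread is (max - min)/mean of the per-method E values;
#' `agreement_flag` is set when it does not exceed `rel_tol`.
#'
#' @param fits A list of at least two `kinetic_fit` objects for one step.
#' @param rel_tol Maximum relative spread counted as agreement. Default 0.10.
#' @return An object of class `consensus_report` with `fits`, `E_mean`,
#'   `E_sd`, `E_relative_spread` and `agreement_flag`.
#' @export
consensus <- function(fits, rel_tol = 0.10) {
  if (inherits(fits, "kinetic_fit")) fits <- list(fits)
  if (length(fits) < 2) ck_stop("consensus needs at least 2 fits", "ck_too_few_fits")
  if (!all(vapply(fits, inherits, logical(1), "kinetic_fit")))
    ck_stop("fits must be kinetic_fit objects", "ck_invalid_fits")
  E <- vapply(fits, `[[`, numeric(1), "E")
  spread <- (max(E) - min(E)) / mean(E)
  structure(
    list(fits = fits, E_mean = mean(E), E_sd = stats::sd(E),
         E_relative_spread = spread, agreement_flag = spread <= rel_tol,
         rel_tol = rel_tol),
    class = "consensus_report"
  )
}

#' @export
print.consensus_report <- function(x, ...) {
  cat(sprintf("<consensus_report> %d methods | E = %.2f +/- %.2f kJ/mol | spread %.1f%% | %s\n",
              length(x$fits), x$E_mean, x$E_sd, 100 * x$E_relative_spread,
              if (x$agreement_flag) "in agreement" else "NOT in agreement"))
  for (f in x$fits) print(f)
  invisible(x)
}

#' Run all four kinetic estimators on one conversion series
#'
#' Convenience wrapper applying [freeman_carroll()], [sharp_wentworth()],
#' [achar()] and [coats_redfern()] to the same step with shared settings.
#'
#' @inheritParams achar
#' @param methods Which estimators to run.
#' @return A named list of `kinetic_fit` objects.
#' @export
fit_all_methods <- function(conv,
                            methods = c("freeman_carroll", "sharp_wentworth",
                                        "achar", "coats_redfern"),
                            n_grid = seq(0.25, 3, by = 0.05),
                            alpha_window = c(0.05, 0.95)) {
  out <- list()
  for (m in methods) {
    out[[m]] <- switch(
      m,
      freeman_carroll = freeman_carroll(conv, alpha_window = alpha_window),
      sharp_wentworth = sharp_wentworth(conv, alpha_window = alpha_window),
      achar = achar(conv, n_grid = n_grid, alpha_window = alpha_window),
      coats_redfern = coats_redfern(conv, n_grid = n_grid, alpha_window = alpha_window),
      ck_stop(paste("unknown method:", m), "ck_unknown_method")
    )
  }
  out
}
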