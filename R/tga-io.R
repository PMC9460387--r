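#' Construct a thermogravimetric curve object
#'
#' The container for one TG run under linear heating: equal-length `time`
#' (min), `temperature` (K, strictly increasing) and `mass` (mg) series, the
#' nominal heating rate `beta` (K/min), the furnace atmosphere and a sample
#' label. `metadata` is a free-form list; the simulator stores ground-truth
#' kinetic parameters there.
#'
#' @param time Time since run start, min.
#' @param temperature Sample temperature, K; strictly increasing.
#' @param mass Sample mass, mg; non-negative.
#' @param beta Nominal heating rate, K/min (> 0).
#' @param atmosphere Furnace gas label, e.g. `"air"` or `"nitrogen"`.
#' @param sample_id Sample label.
#' @param metadata Free-form list.
#' @return An object of class `tga_curve`.
#' @export
tga_curve <- function(time, temperature, mass, beta,
                      atmosphere = "air", sample_id = "sample",
                      metadata = list()) {
  if (length(time) != length(temperature) || length(time) != length(mass))
    ck_stop("time, temperature and mass must have equal length", "ck_invalid_curve")
  if (any(diff(temperature) <= 0))
    ck_stop("temperature must be strictly increasing (linear heating)", "ck_nonmonotone_temperature")
  if (!is_number(beta) || beta <= 0) ck_stop("beta must be > 0 (K/min)", "ck_invalid_curve")
  if (any(mass < 0)) ck_stop("mass must be non-negative", "ck_invalid_curve")
  structure(
    list(time = as.numeric(time), temperature = as.numeric(temperature),
         mass = as.numeric(mass), beta = beta, atmosphere = atmosphere,
         sample_id = sample_id, metadata = metadata),
    class = "tga_curve"
  )
}

#' @export
print.tga_curve <- function(x, ...) {
  cat(sprintf("<tga_curve> %s | %d points | %.1f-%.1f K | beta = %g K/min | %s\n",
              x$sample_id, length(x$mass), min(x$temperature), max(x$temperature),
              x$beta, x$atmosphere))
  invisible(x)
}

#' Write a TG curve as delimited text plus a JSON sidecar
#'
#' The CSV carries columns `time_min`, `temp_C`, `mass_mg`; everything else
#' (heating rate, atmosphere, sample id, and any simulator ground truth) goes
#' to `<path>.json`.
#'
#' @param curve A [tga_curve()].
#' @param path Output CSV path.
#' @param sep Field delimiter.
#' @return `path`, invisibly.
#' @export
write_tga <- function(curve, path, sep = ",") {
  stopifnot(inherits(curve, "tga_curve"))
  df <- data.frame(time_min = curve$time, temp_C = curve$temperature - 273.15,
                   mass_mg = curve$mass)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  sidecar <- list(beta = curve$beta, atmosphere = curve$atmosphere,
                  sample_id = curve$sample_id,
                  metadata = curve$metadata[setdiff(names(curve$metadata), "alpha_true")])
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a TG curve from delimited text
#'
#' Reads a delimited file, maps columns to time/temperature/mass, converts
#' degC to K when asked, validates monotone heating, and estimates the heating
#' rate by regressing temperature on time. If that regression has R^2 below
#' 0.999 the heating program is flagged as nonlinear with a warning (not an
#' error); downstream kinetics use per-point temperatures anyway.
#'
#' @param path Input file path; a `<path>.json` sidecar written by
#'   [write_tga()] is picked up automatically if present.
#' @param column_map Named list mapping `time`, `temperature`, `mass` to the
#'   file's column names.
#' @param celsius Is the temperature column in degC? (converted to K).
#' @param sep Field delimiter.
#' @return A [tga_curve()]; the estimated heating rate is stored as `beta` and
#'   the regression R^2 as `metadata$beta_r_squared`.
#' @export
read_tga <- function(path,
                     column_map = list(time = "time_min", temperature = "temp_C",
                                       mass = "mass_mg"),
                     celsius = TRUE, sep = ",") {
  if (!file.exists(path)) ck_stop(paste("file not found:", path), "ck_missing_file")
  df <- utils::read.csv(path, sep = sep, check.names = FALSE)
  need <- unlist(column_map[c("time", "temperature", "mass")])
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    ck_stop(paste("missing columns:", paste(missing_cols, collapse = ", ")),
            "ck_missing_columns")
  if (nrow(df) < 50) ck_stop("fewer than 50 data points", "ck_too_few_points")
  time <- df[[column_map$time]]
  temp <- df[[column_map$temperature]]
  mass <- df[[column_map$mass]]
  if (celsius) temp <- temp + 273.15
  if (any(diff(temp) <= 0))
    ck_stop("temperature not strictly increasing", "ck_nonmonotone_temperature")

  fit <- stats::lm(temp ~ time)
  beta <- unname(coef(fit)[2])
  r2 <- stats::cor(time, temp)^2
  if (r2 < 0.999)
    warning(sprintf("heating appears nonlinear (R^2 of T~t = %.4f); using per-point temperatures", r2))

  meta <- list(source = path, beta_r_squared = r2)
  atmosphere <- "air"; sample_id <- basename(path)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    atmosphere <- sc$atmosphere %||% atmosphere
    sample_id <- sc$sample_id %||% sample_id
    meta <- c(meta, sc$metadata %||% list())
  }
  tga_curve(time = time, temperature = temp, mass = mass, beta = beta,
            atmosphere = atmosphere, sample_id = sample_id, metadata = meta)
}

#' Differentiate a TG curve (DTG) by Savitzky-Golay filtering
#'
#' Computes the mass-loss rate dw/dt (mg/min) by local least-squares
#' polynomial differentiation of mass against time, and the normalized
#' conversion derivative dalpha/dT = -(dw/dt) / (beta * total mass loss)
#' by the chain rule with the heating rate. The derivative is exact for
#' polynomials up to `polyorder` on the interior; the first and last
#' `(window - 1) / 2` points are edge-affected and returned as `NA` so
#' downstream fits exclude them.
#'
#' @param curve A [tga_curve()] on an (approximately) uniform time grid.
#' @param window Odd filter length, points. Default 11.
#' @param polyorder Local polynomial degree. Default 3. Needs
#'   `window >= polyorder + 2`.
#' @return A data.frame of class `dtg_series` with columns `temperature`
#'   (K), `dw_dt` (mg/min) and `dalpha_dT` (1/K), plus `window`/`polyorder`
#'   attributes.
#' @export
compute_dtg <- function(curve, window = 11, polyorder = 3) {
  stopifnot(inherits(curve, "tga_curve"))
  m <- length(curve$mass)
  if (window %% 2 == 0) ck_stop("window must be odd", "ck_invalid_window")
  if (window < polyorder + 2) ck_stop("window must be >= polyorder + 2", "ck_invalid_window")
  if (window >= m) ck_stop("window must be smaller than the series length", "ck_invalid_window")
  dt <- mean(diff(curve$time))
  dw_dt <- signal::sgolayfilt(curve$mass, p = polyorder, n = window, m = 1, ts = dt)
  h <- (window - 1) / 2
  dw_dt[c(seq_len(h), (m - h + 1):m)] <- NA_real_

  total_loss <- curve$mass[1] - curve$mass[m]
  dalpha_dT <- if (abs(total_loss) > .Machine$double.eps * curve$mass[1] * 100) {
    -dw_dt / (curve$beta * total_loss)
  } else {
    rep(NA_real_, m)
  }
  structure(
    data.frame(temperature = curve$temperature, dw_dt = dw_dt, dalpha_dT = dalpha_dT),
    class = c("dtg_series", "data.frame"),
    window = window, polyorder = polyorder
  )
}

#' Segment a multi-step TG curve at DTG rate minima
#'
#' Finds DTG peaks (local maxima of the mass-loss rate `-dw/dt`) at least
#' `min_peak_fraction` of the global maximum rate, then cuts the temperature
#' axis at the rate minima between consecutive peaks. Hydrated clathrate
#' curves typically segment into a bound-water dehydration step followed by
#' the main decomposition.
#'
#' @param curve A [tga_curve()].
#' @param dtg Its [compute_dtg()] result.
#' @param min_peak_fraction Peak acceptance threshold as a fraction of the
#'   global maximum rate. Default 0.05.
#' @return A data.frame with one row per step: `T_lo`, `T_hi`, `T_peak` (K)
#'   and `peak_rate` (mg/min). Zero rows when no peak clears the threshold.
#' @export
segment_steps <- function(curve, dtg, min_peak_fraction = 0.05) {
  stopifnot(inherits(curve, "tga_curve"), inherits(dtg, "dtg_series"))
  rate <- -dtg$dw_dt             # mass-loss rate, positive during decomposition
  empty <- data.frame(T_lo = numeric(0), T_hi = numeric(0),
                      T_peak = numeric(0), peak_rate = numeric(0))
  w <- attr(dtg, "window") %||% 11
  # extra running-mean smoothing for peak DETECTION only: the point-wise
  # Savitzky-Golay derivative keeps enough noise to fake local maxima, while
  # real decomposition peaks are much wider than the filter window
  k <- 2L * w + 1L
  rate_s <- as.numeric(stats::filter(rate, rep(1 / k, k), sides = 2))
  ok <- which(is.finite(rate_s))
  if (!length(ok)) return(empty)
  rmax <- max(rate_s[ok])
  if (!(rmax > 0)) return(empty)

  thr <- min_peak_fraction * rmax
  # interior points that are the maximum of their +/- k neighborhood
  peaks <- integer(0)
  for (i in ok[ok > min(ok) & ok < max(ok)]) {
    lo <- max(min(ok), i - k); hi <- min(max(ok), i + k)
    nb <- rate_s[lo:hi]
    if (rate_s[i] >= thr && rate_s[i] == max(nb, na.rm = TRUE) &&
        rate_s[i] > rate_s[i - 1]) {
      peaks <- c(peaks, i)
    }
  }
  if (!length(peaks)) return(empty)
  keep <- peaks[c(TRUE, diff(peaks) > k)]
  rate <- rate_s
  Tv <- curve$temperature
  cuts <- numeric(0)
  if (length(keep) > 1) {
    for (j in seq_len(length(keep) - 1)) {
      seg <- keep[j]:keep[j + 1]
      seg <- seg[is.finite(rate[seg])]
      cuts <- c(cuts, Tv[seg[which.min(rate[seg])]])
    }
  }
  bounds <- c(Tv[1], cuts, Tv[length(Tv)])
  data.frame(
    T_lo = bounds[-length(bounds)],
    T_hi = bounds[-1],
    T_peak = Tv[keep],
    peak_rate = rate[keep]
  )
}
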