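#' Define one decomposition step of an nth-order Arrhenius mass-loss model
#'
#' A thermal decomposition step is modelled as a single nth-order reaction
#' with Arrhenius temperature dependence,
#' \deqn{d\alpha/dt = A \exp(-E_a / RT) (1-\alpha)^n,}
#' where \eqn{\alpha} is the conversion of that step (0 at onset, 1 at
#' completion) and the step releases a fixed fraction of the initial sample
#' mass.
#'
#' @param E_a Activation energy, kJ/mol. Must be positive (0 allowed only in
#'   the degenerate testing case `A = 0`).
#' @param A Pre-exponential factor, 1/min. `A = 0` is allowed as a degenerate
#'   zero-rate step for testing.
#' @param n Reaction order (dimensionless, >= 0).
#' @param mass_fraction Fraction of the initial mass lost when this step runs
#'   to completion, in (0, 1].
#' @param label Optional step label; the dehydration step of hydrated
#'   cyclodextrin samples is conventionally labelled `"dehydration"`.
#' @return An object of class `decomposition_step`.
#' @seealso [sim_spec()], [simulate_tga()]
#' @export
decomposition_step <- function(E_a, A, n = 1, mass_fraction = 1, label = NULL) {
  if (!is_number(E_a) || E_a < 0) ck_stop("E_a must be a non-negative number (kJ/mol)", "ck_invalid_step")
  if (!is_number(A) || A < 0) ck_stop("A must be a non-negative number (1/min)", "ck_invalid_step")
  if (A > 0 && E_a == 0) ck_stop("E_a must be > 0 for an active step", "ck_invalid_step")
  if (!is_number(n) || n < 0) ck_stop("reaction order n must be >= 0", "ck_invalid_step")
  if (!is_number(mass_fraction) || mass_fraction <= 0 || mass_fraction > 1)
    ck_stop("mass_fraction must lie in (0, 1]", "ck_invalid_step")
  structure(
    list(E_a = E_a, A = A, n = n, mass_fraction = mass_fraction, label = label),
    class = "decomposition_step"
  )
}

#' Specify a synthetic thermogravimetric experiment
#'
#' Bundles the decomposition steps with the instrument program: linear heating
#' at rate `beta` from `T_start` to `T_end`, an evenly spaced temperature grid
#' of `n_points` samples, initial mass `m0`, and additive i.i.d. Gaussian mass
#' noise of standard deviation `noise_sd * m0`.
#'
#' @param steps A `decomposition_step` or list of them; their mass fractions
#'   must sum to at most 1.
#' @param beta Linear heating rate, K/min (> 0). Default 10 K/min, the
#'   standard program for cyclodextrin clathrate runs.
#' @param T_start,T_end Temperature bounds, K (`T_start < T_end`).
#' @param n_points Number of grid points (>= 50).
#' @param noise_sd Mass noise standard deviation as a fraction of `m0` (>= 0).
#' @param m0 Initial sample mass, mg.
#' @param seed Integer seed for the noise generator; `NULL` leaves the RNG
#'   state alone.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(steps, beta = 10, T_start = 303.15, T_end = 823.15,
                     n_points = 1500, noise_sd = 0, m0 = 10, seed = NULL) {
  if (inherits(steps, "decomposition_step")) steps <- list(steps)
  if (!length(steps) || !all(vapply(steps, inherits, logical(1), "decomposition_step")))
    ck_stop("steps must be a list of decomposition_step objects", "ck_invalid_spec")
  if (sum(vapply(steps, `[[`, numeric(1), "mass_fraction")) > 1 + 1e-12)
    ck_stop("step mass fractions must sum to <= 1", "ck_invalid_spec")
  if (!is_number(beta) || beta <= 0) ck_stop("beta must be > 0 (K/min)", "ck_invalid_spec")
  if (!is_number(T_start) || !is_number(T_end) || T_start >= T_end)
    ck_stop("need T_start < T_end (K)", "ck_invalid_spec")
  if (!is_number(n_points) || n_points < 50) ck_stop("n_points must be >= 50", "ck_invalid_spec")
  if (!is_number(noise_sd) || noise_sd < 0) ck_stop("noise_sd must be >= 0", "ck_invalid_spec")
  if (!is_number(m0) || m0 <= 0) ck_stop("m0 must be > 0 (mg)", "ck_invalid_spec")
  structure(
    list(steps = steps, beta = beta, T_start = T_start, T_end = T_end,
         n_points = as.integer(n_points), noise_sd = noise_sd, m0 = m0,
         seed = seed),
    class = "sim_spec"
  )
}

# Conversion rate dalpha/dT (1/K) for one step; clamped so (1-alpha) never
# goes negative under sub-step overshoot.
step_rate <- function(Tk, alpha, step, beta) {
  E <- step$E_a * 1000
  r <- (step$A / beta) * exp(-E / (R_GAS * Tk)) * pmax(1 - alpha, 0)^step$n
  if (any(!is.finite(r)))
    ck_stop(sprintf("non-finite decomposition rate in step '%s' (E_a = %g kJ/mol)",
                    step$label %||% "unnamed", step$E_a), "ck_integration_failure")
  r
}

# Fixed-step classical RK4 in temperature for one step's alpha(T) on the
# supplied grid, sub-stepping whenever the projected dalpha over one grid
# interval exceeds `max_dalpha`.
integrate_step_alpha <- function(Tk, step, beta, max_dalpha = 0.01) {
  m <- length(Tk)
  alpha <- numeric(m)
  for (i in seq_len(m - 1)) {
    h <- Tk[i + 1] - Tk[i]
    a <- alpha[i]
    k1 <- step_rate(Tk[i], a, step, beta)
    nsub <- max(1L, ceiling(k1 * h / max_dalpha))
    hs <- h / nsub
    T0 <- Tk[i]
    for (s in seq_len(nsub)) {
      k1 <- step_rate(T0, a, step, beta)
      k2 <- step_rate(T0 + hs / 2, a + hs * k1 / 2, step, beta)
      k3 <- step_rate(T0 + hs / 2, a + hs * k2 / 2, step, beta)
      k4 <- step_rate(T0 + hs, a + hs * k3, step, beta)
      a <- a + hs * (k1 + 2 * k2 + 2 * k3 + k4) / 6
      if (a > 1) a <- 1
      T0 <- T0 + hs
    }
    alpha[i + 1] <- a
  }
  alpha
}

#' Simulate a thermogravimetric (TG) curve with known kinetics
#'
#' Integrates each step's conversion \eqn{d\alpha/dT = (A/\beta)
#' \exp(-E_a/RT)(1-\alpha)^n} with \eqn{\alpha(T_{start}) = 0} by fixed-step
#' 4th-order Runge-Kutta on the temperature grid (with internal sub-stepping
#' when one grid interval would advance \eqn{\alpha} by more than 0.01), then
#' assembles the mass signal
#' \deqn{m(T) = m_0 \bigl(1 - \sum_s f_s\,\alpha_s(T)\bigr) + \epsilon,}
#' with \eqn{f_s} the per-step mass fractions and \eqn{\epsilon} seeded i.i.d.
#' Gaussian noise of sd `noise_sd * m0`.
#'
#' The returned curve's `metadata` records the ground-truth parameters, the
#' noiseless per-step conversion, each step's DTG-peak temperature (the grid
#' temperature maximizing its noiseless \eqn{d\alpha/dT}), the step-completion
#' temperature (first grid point with \eqn{\alpha \ge 0.999}, `NA` if never
#' reached) and whether any noisy mass had to be clipped at zero.
#'
#' @param spec A [sim_spec()].
#' @return A [tga_curve()] with ground-truth metadata.
#' @examples
#' sp <- sim_spec(decomposition_step(E_a = 150, A = 1e12, n = 1),
#'                T_start = 450, T_end = 750, n_points = 600)
#' curve <- simulate_tga(sp)
#' curve$metadata$dtg_peak_K
#' @export
simulate_tga <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  Tk <- seq(spec$T_start, spec$T_end, length.out = spec$n_points)
  time <- (Tk - spec$T_start) / spec$beta
  alphas <- lapply(spec$steps, integrate_step_alpha, Tk = Tk, beta = spec$beta)
  fr <- vapply(spec$steps, `[[`, numeric(1), "mass_fraction")
  loss <- Reduce(`+`, Map(function(a, f) f * a, alphas, fr))
  mass <- spec$m0 * (1 - loss)

  step_meta <- Map(function(st, a, f) {
    rate <- step_rate(Tk, a, st, spec$beta)
    done <- which(a >= 0.999)
    list(E_a = st$E_a, A = st$A, n = st$n, mass_fraction = f,
         label = st$label,
         dtg_peak_K = Tk[which.max(rate)],
         completion_K = if (length(done)) Tk[done[1]] else NA_real_)
  }, spec$steps, alphas, fr)

  clipped <- FALSE
  if (spec$noise_sd > 0) {
    if (!is.null(spec$seed)) set.seed(spec$seed)
    mass <- mass + rnorm(length(mass), sd = spec$noise_sd * spec$m0)
    if (any(mass < 0)) {
      mass[mass < 0] <- 0
      clipped <- TRUE
    }
  }

  tga_curve(
    time = time, temperature = Tk, mass = mass, beta = spec$beta,
    atmosphere = "air", sample_id = "synthetic",
    metadata = list(
      ground_truth = step_meta,
      alpha_true = alphas,
      m0 = spec$m0, noise_sd = spec$noise_sd, seed = spec$seed,
      clipped_negative_mass = clipped
    )
  )
}

#' Default step models for a hydrated cyclodextrin clathrate
#'
#' `dehydration_step()` models loss of cavity-bound water: hydrated
#' beta-cyclodextrin carries roughly 13% water by mass and releases it as a
#' low-temperature endotherm; the default Arrhenius parameters place the
#' derivative-thermogravimetry (DTG) peak near 90 degC at 10 K/min.
#' `main_decomposition_step()` models the principal oxidative decomposition of
#' the host skeleton (~330-350 degC at 10 K/min).
#'
#' @param E_a,A,n,mass_fraction As in [decomposition_step()].
#' @return A `decomposition_step`.
#' @export
dehydration_step <- function(E_a = 65, A = 1.35e9, n = 1, mass_fraction = 0.13) {
  decomposition_step(E_a, A, n, mass_fraction, label = "dehydration")
}

#' @rdname dehydration_step
#' @export
main_decomposition_step <- function(E_a = 150, A = 1e12, n = 1, mass_fraction = 0.65) {
  decomposition_step(E_a, A, n, mass_fraction, label = "main")
}

#' Simulate a TG curve with an explicit bound-water dehydration step
#'
#' Identical to [simulate_tga()] but requires the first step to carry the
#' label `"dehydration"`, and records the achieved dehydration DTG-peak
#' temperature (in degC as well as K) at the top level of the metadata. With
#' the package defaults ([dehydration_step()]) this peak falls in the 70-109
#' degC window where the dehydration endotherm of hydrated cyclodextrin
#' clathrates is observed.
#'
#' @param spec A [sim_spec()] whose first step is labelled `"dehydration"`.
#' @return A [tga_curve()]; `metadata$dehydration_peak_C` holds the achieved
#'   DTG-peak temperature of the first step in degC.
#' @export
simulate_dehydration_profile <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  lab <- spec$steps[[1]]$label
  if (is.null(lab) || !identical(lab, "dehydration"))
    ck_stop("first step must be labelled 'dehydration'", "ck_missing_dehydration_label")
  curve <- simulate_tga(spec)
  peak_K <- curve$metadata$ground_truth[[1]]$dtg_peak_K
  curve$metadata$dehydration_peak_K <- peak_K
  curve$metadata$dehydration_peak_C <- peak_K - 273.15
  curve
}

#' Simulate paired free/complex chemical-shift tables
#'
#' Emulates the paired assignment tables used in host-guest NMR work: for each
#' site the free-species shift is \eqn{\delta_0} and the complexed-species
#' shift is \eqn{\delta_0 + \Delta\delta}, each perturbed by independent
#' Gaussian measurement noise. With `noise_sd = 0` the planted
#' \eqn{\Delta\delta} round-trips exactly through [compute_delta()].
#'
#' @param true_shifts A data.frame with columns `nucleus`, `molecule`, `site`,
#'   `delta0` (ppm) and `ddelta` (ppm, the planted displacement).
#' @param noise_sd Per-measurement noise sd, ppm (>= 0).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A list with data.frames `free` and `complex`, each with columns
#'   `nucleus`, `molecule`, `site`, `delta_ppm`.
#' @export
simulate_shift_tables <- function(true_shifts, noise_sd = 0, seed = NULL) {
  req <- c("nucleus", "molecule", "site", "delta0", "ddelta")
  if (!all(req %in% names(true_shifts)))
    ck_stop(paste("true_shifts needs columns:", paste(req, collapse = ", ")),
            "ck_invalid_shift_spec")
  if (!is_number(noise_sd) || noise_sd < 0) ck_stop("noise_sd must be >= 0", "ck_invalid_shift_spec")
  key <- paste(true_shifts$nucleus, true_shifts$molecule, true_shifts$site)
  if (anyDuplicated(key))
    ck_stop(paste("duplicate site labels:",
                  paste(unique(key[duplicated(key)]), collapse = "; ")),
            "ck_duplicate_sites")
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(true_shifts)
  e1 <- if (noise_sd > 0) rnorm(m, sd = noise_sd) else numeric(m)
  e2 <- if (noise_sd > 0) rnorm(m, sd = noise_sd) else numeric(m)
  base <- true_shifts[c("nucleus", "molecule", "site")]
  list(
    free = cbind(base, delta_ppm = true_shifts$delta0 + e1),
    complex = cbind(base, delta_ppm = true_shifts$delta0 + true_shifts$ddelta + e2)
  )
}
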