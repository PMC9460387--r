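# Shared scenario builders and independent oracles.

R_GAS_TEST <- 8.314

# Kissinger relation: temperature of the maximum decomposition rate for a
# first-order step; used only to center simulation windows on the transition.
kissinger_peak_T <- function(E, A, beta = 10) {
  f <- function(Tk) {
    log(A) - E * 1000 / (R_GAS_TEST * Tk) -
      log(E * 1000 * beta / (R_GAS_TEST * Tk^2))
  }
  stats::uniroot(f, c(250, 2500))$root
}

# One single-step scenario centered on its DTG peak. Higher-order steps have
# long conversion tails, so their window extends further past the peak to run
# the step to completion before the curve ends.
.scenario_cache <- new.env(parent = emptyenv())
make_step_scenario <- function(E = 150, A = 1e12, n = 1, beta = 10,
                               n_points = 2000, noise_sd = 0, seed = NULL) {
  key <- paste(E, A, n, beta, n_points, noise_sd, seed %||% "NULL", sep = "|")
  if (!is.null(.scenario_cache[[key]])) return(.scenario_cache[[key]])
  Tp <- kissinger_peak_T(E, A, beta)
  spec <- sim_spec(decomposition_step(E, A, n),
                   beta = beta, T_start = Tp - 170,
                   T_end = Tp + if (n > 1.5) 400 else 140,
                   n_points = n_points, noise_sd = noise_sd, seed = seed)
  curve <- simulate_tga(spec)
  dtg <- compute_dtg(curve)
  conv <- compute_conversion(curve, range(curve$temperature), dtg)
  out <- list(spec = spec, curve = curve, dtg = dtg, conv = conv, E = E, A = A, n = n)
  .scenario_cache[[key]] <- out
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent ordinary-least-squares oracle: explicit normal-equation sums,
# no model-matrix machinery shared with the implementation.
ols_oracle <- function(x, y) {
  m <- length(x)
  sx <- sum(x); sy <- sum(y)
  slope <- (m * sum(x * y) - sx * sy) / (m * sum(x * x) - sx^2)
  intercept <- (sy - slope * sx) / m
  list(slope = slope, intercept = intercept)
}

# Brute-force band assignment oracle: enumerate all injective partial
# matchings within tolerance, keep maximum cardinality, then minimum total
# distance. Exponential; only for lists of <= 6 peaks.
brute_force_match <- function(free, complex, tolerance) {
  nf <- length(free); nc <- length(complex)
  best <- list(card = -1, dist = Inf, pairs = NULL)
  rec <- function(i, used, pairs, dist) {
    if (i > nf) {
      card <- nrow(pairs)
      if (card > best$card || (card == best$card && dist < best$dist - 1e-12)) {
        best <<- list(card = card, dist = dist, pairs = pairs)
      }
      return(invisible())
    }
    rec(i + 1, used, pairs, dist)                       # leave free[i] unmatched
    for (j in seq_len(nc)) {
      d <- abs(free[i] - complex[j])
      if (!used[j] && d <= tolerance) {
        used2 <- used; used2[j] <- TRUE
        rec(i + 1, used2, rbind(pairs, data.frame(free = free[i], complex = complex[j])),
            dist + d)
      }
    }
  }
  rec(1, logical(nc), data.frame(free = numeric(0), complex = numeric(0)), 0)
  if (best$card > 0) best$pairs[order(best$pairs$free), , drop = FALSE]
  else data.frame(free = numeric(0), complex = numeric(0))
}
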