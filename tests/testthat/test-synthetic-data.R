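test_that("degenerate zero-rate step leaves the mass constant", {
  sp <- sim_spec(decomposition_step(E_a = 0, A = 0, n = 1, mass_fraction = 0.5),
                 T_start = 350, T_end = 750, n_points = 100)
  cv <- simulate_tga(sp)
  expect_equal(cv$mass, rep(10, 100))
})

test_that("noise-free simulation is deterministic and seed-bit-identical", {
  sp1 <- sim_spec(decomposition_step(150, 1e12), T_start = 450, T_end = 750,
                  n_points = 200, noise_sd = 0, seed = 1)
  sp2 <- sim_spec(decomposition_step(150, 1e12), T_start = 450, T_end = 750,
                  n_points = 200, noise_sd = 0, seed = 999)
  expect_identical(simulate_tga(sp1)$mass, simulate_tga(sp2)$mass)

  spn <- sim_spec(decomposition_step(150, 1e12), T_start = 450, T_end = 750,
                  n_points = 200, noise_sd = 0.01, seed = 42)
  expect_identical(simulate_tga(spn)$mass, simulate_tga(spn)$mass)
  spn2 <- sim_spec(decomposition_step(150, 1e12), T_start = 450, T_end = 750,
                   n_points = 200, noise_sd = 0.01, seed = 43)
  expect_false(identical(simulate_tga(spn)$mass, simulate_tga(spn2)$mass))
})

test_that("RK4 conversion matches an independent fine-grid ODE integration", {
  skip_if_not_installed("deSolve")
  sp <- sim_spec(decomposition_step(E_a = 150, A = 1e12, n = 1),
                 T_start = 350, T_end = 750, n_points = 2000)
  cv <- simulate_tga(sp)
  a <- cv$metadata$alpha_true[[1]]
  T_half_rk4 <- stats::approx(a, cv$temperature, xout = 0.5, ties = "ordered")$y

  rate <- function(Tk, y, p) {
    list((1e12 / 10) * exp(-150000 / (8.314 * Tk)) * max(1 - y[1], 0))
  }
  Ts <- seq(350, 750, length.out = 40001)
  sol <- deSolve::lsoda(c(a = 0), Ts, rate, NULL, rtol = 1e-10, atol = 1e-12)
  T_half_ode <- stats::approx(sol[, "a"], sol[, 1], xout = 0.5, ties = "ordered")$y

  expect_equal(T_half_ode, 628.3030, tolerance = 1e-5)  # frozen oracle value
  expect_lt(abs(T_half_rk4 - T_half_ode), 0.5)
})

test_that("noiseless mass is conserved and per-step conversion is monotone in [0,1]", {
  sp <- sim_spec(list(decomposition_step(65, 1.35e9, 1, 0.1),
                      decomposition_step(150, 1e12, 1, 0.6)),
                 T_start = 303, T_end = 823, n_points = 1200)
  cv <- simulate_tga(sp)
  m <- length(cv$mass)
  expect_lt(abs(cv$mass[m] - 10 * (1 - 0.1 - 0.6)), 1e-6 * 10)
  for (a in cv$metadata$alpha_true) {
    expect_true(all(diff(a) >= 0))
    expect_true(all(a >= 0 & a <= 1))
  }
})

test_that("raising the heating rate shifts the DTG peak to higher temperature", {
  peaks <- vapply(c(5, 10, 20), function(b) {
    sp <- sim_spec(decomposition_step(150, 1e12), beta = b,
                   T_start = 430, T_end = 840, n_points = 1500)
    simulate_tga(sp)$metadata$ground_truth[[1]]$dtg_peak_K
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
})

test_that("default dehydration step peaks inside the 70-109 degC window", {
  sp <- sim_spec(list(dehydration_step(), main_decomposition_step()))
  cv <- simulate_dehydration_profile(sp)
  expect_gte(cv$metadata$dehydration_peak_C, 70)
  expect_lte(cv$metadata$dehydration_peak_C, 109)
})

test_that("dehydration profile requires the dehydration label on step 1", {
  sp <- sim_spec(list(main_decomposition_step(), dehydration_step()))
  expect_error(simulate_dehydration_profile(sp), class = "ck_missing_dehydration_label")
})

test_that("two-step fractions 0.1 + 0.6 leave 30% of the initial mass", {
  sp <- sim_spec(list(dehydration_step(mass_fraction = 0.1),
                      main_decomposition_step(mass_fraction = 0.6)),
                 T_start = 303, T_end = 823, n_points = 1000,
                 noise_sd = 0.002, seed = 11)
  cv <- simulate_dehydration_profile(sp)
  expect_equal(cv$mass[length(cv$mass)], 0.3 * 10, tolerance = 0.01)
})

test_that("invalid specs are rejected with typed errors", {
  expect_error(decomposition_step(-1, 1e12), class = "ck_invalid_step")
  expect_error(decomposition_step(150, 1e12, mass_fraction = 1.2), class = "ck_invalid_step")
  expect_error(sim_spec(list(decomposition_step(100, 1, 1, 0.7),
                             decomposition_step(100, 1, 1, 0.7))),
               class = "ck_invalid_spec")
  expect_error(sim_spec(decomposition_step(100, 1), T_start = 700, T_end = 600),
               class = "ck_invalid_spec")
  expect_error(sim_spec(decomposition_step(100, 1), n_points = 10), class = "ck_invalid_spec")
})

test_that("shift-table simulation round-trips planted displacements at zero noise", {
  truth <- data.frame(nucleus = "1H", molecule = "host",
                      site = c("3", "5"), delta0 = c(3.49, 3.45),
                      ddelta = c(0.110, 0))
  tabs <- simulate_shift_tables(truth, noise_sd = 0)
  rec <- compute_delta(tabs$free, tabs$complex)
  expect_equal(rec$delta_delta[rec$site == "3"], 0.110)
  expect_equal(rec$delta_delta[rec$site == "5"], 0)
})

test_that("duplicate site labels in a shift spec are rejected", {
  truth <- data.frame(nucleus = "1H", molecule = "host",
                      site = c("3", "3"), delta0 = c(3.49, 3.45),
                      ddelta = c(0.1, 0.2))
  expect_error(simulate_shift_tables(truth), class = "ck_duplicate_sites")
})

test_that("noisy shift recovery has the closed-form sqrt(2) * noise_sd spread", {
  m <- 1000
  truth <- data.frame(nucleus = "1H", molecule = "host",
                      site = sprintf("s%04d", seq_len(m)),
                      delta0 = runif(m, 1, 9), ddelta = runif(m, -0.2, 0.2))
  tabs <- simulate_shift_tables(truth, noise_sd = 0.01, seed = 5)
  rec <- compute_delta(tabs$free, tabs$complex)
  err <- rec$delta_delta[match(truth$site, rec$site)] - truth$ddelta
  expect_lt(abs(sd(err) - sqrt(2) * 0.01) / (sqrt(2) * 0.01), 0.20)
})
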