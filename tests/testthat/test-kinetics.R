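# A fabricated conversion series with exactly linear transformed coordinates;
# used for the regression-identity checks.
fake_conv <- function(temperature, alpha, dalpha_dT, dw_dt, w_r, beta = 10, w_c = 1) {
  structure(
    data.frame(temperature = temperature, alpha = alpha,
               dalpha_dT = dalpha_dT, dw_dt = dw_dt, w_r = w_r),
    class = c("conversion_series", "data.frame"), beta = beta, w_c = w_c
  )
}

test_that("conversion hits its boundary values and tracks the simulator truth", {
  sc <- make_step_scenario(E = 150, A = 1e12, n = 1)
  conv <- sc$conv
  expect_equal(conv$alpha[1], 0)
  expect_equal(conv$alpha[nrow(conv)], 1)
  expect_equal(conv$w_r[1], attr(conv, "w_c"))
  expect_equal(conv$w_r[nrow(conv)], 0)
  expect_true(all(diff(conv$w_r) <= 1e-12))
  a_true <- sc$curve$metadata$alpha_true[[1]]
  expect_lt(max(abs(conv$alpha - a_true)), 1e-3)
})

test_that("conversion rejects steps without mass loss", {
  tm <- seq(0, 20, by = 0.05)
  flat <- tga_curve(time = tm, temperature = 300 + 10 * tm,
                    mass = rep(10, length(tm)), beta = 10)
  expect_error(compute_conversion(flat, c(320, 450)), class = "ck_zero_mass_loss")
  sc <- make_step_scenario(E = 150, A = 1e12, n = 1)
  expect_error(compute_conversion(sc$curve, c(100, 200)),
               class = "ck_invalid_step_interval")
})

test_that("all four methods recover E and n on clean nth-order curves", {
  tol <- c(freeman_carroll = 0.05, sharp_wentworth = 0.03,
           achar = 0.03, coats_redfern = 0.02)
  for (E in c(100, 150, 250)) {
    for (n in c(1, 2)) {
      sc <- make_step_scenario(E = E, A = 1e12, n = n)
      methods <- if (n == 1) names(tol) else setdiff(names(tol), "sharp_wentworth")
      fits <- fit_all_methods(sc$conv, methods = methods)
      for (m in methods) {
        expect_lt(abs(fits[[m]]$E - E) / E, tol[[m]],
                  label = sprintf("%s E rel.err (E=%g, n=%g)", m, E, n))
      }
      expect_lt(abs(fits$freeman_carroll$n - n), 0.2)
      expect_equal(fits$achar$n, n, tolerance = 1e-9)
      expect_equal(fits$coats_redfern$n, n, tolerance = 1e-9)
      cons <- consensus(fits)
      expect_true(cons$agreement_flag,
                  label = sprintf("consensus at rel_tol 0.10 (E=%g, n=%g)", E, n))
    }
  }
})

test_that("Coats-Redfern recovers the pre-exponential factor on clean data", {
  sc <- make_step_scenario(E = 150, A = 1e12, n = 1)
  fit <- coats_redfern(sc$conv)
  expect_lt(abs(log10(fit$A) - 12), 0.5)
})

test_that("Freeman-Carroll returns exact slope/intercept on exactly linear pairs", {
  # log10 rate = s / T + b * log10 w_r + const  =>  Y = s X + b exactly
  s <- -7000; b <- 1.3
  Tk <- seq(500, 600, length.out = 60)
  w_r <- seq(1, 0.05, length.out = 60)
  rate <- 10^(s / Tk + b * log10(w_r) + 2)
  conv <- fake_conv(Tk, alpha = seq(0.1, 0.9, length.out = 60),
                    dalpha_dT = rate / 10, dw_dt = -rate, w_r = w_r)
  fit <- freeman_carroll(conv, alpha_window = c(0, 1))
  expect_equal(fit$slope, s, tolerance = 1e-10)
  expect_equal(fit$n, b, tolerance = 1e-10)
})

test_that("Freeman-Carroll rejects constant w_r as degenerate", {
  Tk <- seq(500, 600, length.out = 30)
  conv <- fake_conv(Tk, alpha = seq(0.1, 0.9, length.out = 30),
                    dalpha_dT = rep(1e-3, 30), dw_dt = rep(-0.01, 30),
                    w_r = rep(0.5, 30))
  expect_error(freeman_carroll(conv, alpha_window = c(0, 1)),
               class = "ck_degenerate_fit")
})

test_that("Sharp-Wentworth recovers exact lines and flags order misfit", {
  s <- -7835.9; cint <- 11
  Tk <- seq(550, 700, length.out = 50)
  alpha <- seq(0.05, 0.95, length.out = 50)
  dadT <- (1 - alpha) * 10^(cint + s / Tk)
  conv <- fake_conv(Tk, alpha, dadT, dw_dt = -dadT * 10, w_r = 1 - alpha)
  fit <- sharp_wentworth(conv, alpha_window = c(0, 1))
  expect_equal(fit$slope, s, tolerance = 1e-8)
  expect_equal(fit$intercept, cint, tolerance = 1e-8)
  expect_equal(fit$A, 10 * 10^cint, tolerance = 1e-6)

  r2_first <- sharp_wentworth(make_step_scenario(150, 1e12, 1)$conv)$r_squared
  r2_second <- sharp_wentworth(make_step_scenario(150, 1e12, 2)$conv)$r_squared
  expect_gt(r2_first, r2_second)
})

test_that("order-grid methods prefer the true order on clean data", {
  sc1 <- make_step_scenario(E = 150, A = 1e12, n = 1)
  restricted <- coats_redfern(sc1$conv, n_grid = 2)
  free <- coats_redfern(sc1$conv, n_grid = c(1, 2))
  expect_equal(free$n, 1)
  expect_lt(restricted$r_squared, free$r_squared)

  a2 <- achar(make_step_scenario(E = 150, A = 1e12, n = 2)$conv,
              n_grid = c(0.5, 1, 1.5, 2))
  expect_equal(a2$n, 2)
})

test_that("integral model g(alpha) has the analytic small-alpha limit", {
  a <- 10^seq(-8, -4)
  expect_equal(-log(1 - a) / a, rep(1, length(a)), tolerance = 1e-4)
  for (n in c(0.5, 2, 3)) {
    g <- (1 - (1 - a)^(1 - n)) / (1 - n)
    expect_equal(g / a, rep(1, length(a)), tolerance = 1e-3)
  }
})

test_that("every linearization equals an independent normal-equation fit to 1e-10", {
  sc <- make_step_scenario(E = 150, A = 1e12, n = 1)
  fits <- fit_all_methods(sc$conv)
  for (f in fits) {
    o <- ols_oracle(f$points$x, f$points$y)
    expect_equal(f$slope, o$slope, tolerance = 1e-10, label = paste(f$method, "slope"))
    expect_equal(f$intercept, o$intercept, tolerance = 1e-10,
                 label = paste(f$method, "intercept"))
  }
})

test_that("kinetic estimates are invariant to mass rescaling", {
  sc <- make_step_scenario(E = 150, A = 1e12, n = 1)
  cv2 <- sc$curve
  cv2$mass <- cv2$mass * 3.7
  conv2 <- compute_conversion(cv2, range(cv2$temperature), compute_dtg(cv2))
  f1 <- fit_all_methods(sc$conv)
  f2 <- fit_all_methods(conv2)
  for (m in names(f1)) {
    expect_equal(f2[[m]]$E, f1[[m]]$E, tolerance = 1e-8)
    expect_equal(f2[[m]]$n, f1[[m]]$n, tolerance = 1e-8)
  }
})

test_that("shrinking the fit window barely moves E on clean data", {
  sc <- make_step_scenario(E = 150, A = 1e12, n = 1)
  for (fitter in list(freeman_carroll, sharp_wentworth, achar, coats_redfern)) {
    wide <- fitter(sc$conv, alpha_window = c(0.05, 0.95))
    narrow <- fitter(sc$conv, alpha_window = c(0.15, 0.85))
    expect_lt(abs(narrow$E - wide$E) / wide$E, 0.02)
  }
})

test_that("consensus arithmetic and edge cases", {
  mk <- function(E) clathrakit:::kinetic_fit("achar", E, 1, 1e12, -1, 1, 0.999,
                                             c(0.05, 0.95), 100)
  rep2 <- consensus(list(mk(100), mk(300)), rel_tol = 0.1)
  expect_equal(rep2$E_relative_spread, 1.0)
  expect_false(rep2$agreement_flag)
  expect_equal(rep2$E_mean, 200)
  expect_error(consensus(list(mk(100))), class = "ck_too_few_fits")
})
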