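R_kcal <- 1.9872e-3

test_that("Arrhenius rate constant obeys its defining identities", {
  p <- arrhenius_params(111.1, 315.6, 250)
  expect_equal(rate_constant(p, 315.6), 1.0)

  ## E_A = 0 degenerates to k = 1 everywhere
  p0 <- suppressWarnings(arrhenius_params(0, 315.6, 250))
  expect_equal(rate_constant(p0, c(280, 315.6, 350)), rep(1, 3))

  ## frozen value from independent high-precision evaluation of the
  ## exponential: E_A = 111.1, T* = 315.6, T = 320.6
  expect_equal(rate_constant(p, 320.6), 15.84339, tolerance = 1e-6)

  ## monotone increasing in T
  Tg <- seq(290, 340, by = 0.5)
  expect_true(all(diff(rate_constant(p, Tg)) > 0))
})

test_that("simulated transition has the model's limiting and integral properties", {
  p <- arrhenius_params(111.1, 315.6, 250)

  ## low-temperature limit: integral ~ 0, Cp_ex -> (dH/nu) k(T)
  Tlow <- seq(270, 272, by = 0.1)
  tg_low <- excess_heat_capacity(p, Tlow, 1)
  expect_equal(tg_low$Cp_ex, 250 * rate_constant(p, Tlow), tolerance = 1e-4)

  ## conservation: area over a grid extending 40 K past the peak = dH
  Tm <- peak_temperature(p, 1)
  grid <- seq(Tm - 35, Tm + 40, by = 0.1)
  tg <- excess_heat_capacity(p, grid, 1)
  expect_true(all(tg$Cp_ex >= 0))
  area <- pracma::trapz(tg$T, tg$Cp_ex)
  expect_lt(abs(area - 250) / 250, 0.005)

  ## single interior maximum: strictly rising, then falling (the far
  ## tail underflows to exactly zero once the native state is exhausted)
  ipk <- which.max(tg$Cp_ex)
  expect_true(ipk > 1 && ipk < length(grid))
  expect_true(all(diff(tg$Cp_ex[1:ipk]) > 0))
  fall <- tg$Cp_ex[ipk:length(grid)]
  expect_true(all(diff(fall) <= 0))
  expect_true(all(diff(fall[fall > 1e-10 * max(fall)]) < 0))

  expect_warning(excess_heat_capacity(p, seq(300, 330, by = 1), 1), "0.5 K")
})

test_that("grid-based kinetic integral matches adaptive quadrature", {
  ## recover the model's inner integral from the simulated curve,
  ## I(T) = -nu * log(Cp_ex * nu / (dH * k)), and compare it with
  ## adaptive quadrature of the rate constant
  p <- arrhenius_params(111.1, 315.6, 250)
  grid <- seq(295, 325, by = 0.1)
  tg <- excess_heat_capacity(p, grid, 1)
  I_grid <- -log(tg$Cp_ex / (250 * rate_constant(p, grid)))
  probe <- seq(10, length(grid), by = 40)
  for (i in probe) {
    I_ref <- integrate(function(x) rate_constant(p, x), grid[1], grid[i],
                       rel.tol = 1e-10)$value
    expect_lt(abs(I_grid[i] - I_ref) / max(I_ref, 1e-12), 1e-4)
  }
})

test_that("closed-form peak temperature agrees with the simulated maximum", {
  p <- arrhenius_params(111.1, 315.6, 250)
  Tm <- peak_temperature(p, 1)
  grid <- seq(p$T_star - 25, p$T_star + 15, by = 0.01)
  tg <- excess_heat_capacity(p, grid, 1)
  expect_lt(abs(Tm - grid[which.max(tg$Cp_ex)]), 0.011)

  ## peak condition k(Tm) = nu E_A / (R Tm^2) holds at the root
  expect_equal(rate_constant(p, Tm), 1 * p$E_A / (R_kcal * Tm^2),
               tolerance = 1e-8)

  ## kinetic control: T_m increases with scan rate and with T*
  expect_gt(peak_temperature(p, 2), Tm)
  p2 <- arrhenius_params(111.1, 317.6, 250)
  expect_gt(peak_temperature(p2, 1), Tm)
})

test_that("thermogram fit recovers generating parameters", {
  p <- arrhenius_params(111.1, 315.6, 250)
  tg <- gen_thermogram(p, scan_rate = 1, noise_abs = 0, seed = 1)
  fit <- fit_thermogram(tg)
  expect_equal(fit$params$E_A, 111.1, tolerance = 1e-3)
  expect_equal(fit$params$T_star, 315.6, tolerance = 1e-3)
  expect_equal(fit$params$dH_cal, 250, tolerance = 1e-3)
  expect_equal(fit$quality, 1.0, tolerance = 1e-10)

  ## truncated transitions are rejected
  cut <- seq(295, 313, by = 0.1)
  tg_cut <- excess_heat_capacity(p, cut, 1)
  expect_error(fit_thermogram(tg_cut), "truncated")
})

test_that("scan-rate misspecification shifts T* by its closed-form amount", {
  ## the model is exactly degenerate under scan-rate rescaling: refitting
  ## a curve recorded at 1 K/min as if it were 2 K/min reproduces E_A and
  ## dH exactly while biasing T* by 1/T*' = 1/T* + R ln(2)/E_A
  p <- arrhenius_params(111.1, 315.6, 250)
  tg <- gen_thermogram(p, scan_rate = 1, noise_abs = 0, seed = 1)
  wrong <- fit_thermogram(thermogram(tg$T, tg$Cp_ex, scan_rate = 2))
  T_star_shifted <- 1 / (1 / 315.6 + R_kcal * log(2) / 111.1)
  expect_equal(wrong$params$T_star, T_star_shifted, tolerance = 1e-4)
  expect_gt(abs(wrong$params$T_star - 315.6), 1)  # T* is NOT recovered
  expect_equal(wrong$params$E_A, 111.1, tolerance = 1e-3)
})

test_that("goodness_r matches its defining formula", {
  y <- c(1, 2, 3)
  expect_equal(goodness_r(y, y), 1.0)
  expect_equal(goodness_r(y, rep(mean(y), 3)), 0.0)
  expect_equal(goodness_r(y, c(1, 2, 4)), 0.5)
  expect_error(goodness_r(rep(2, 5), rep(2, 5)), "constant")
})

test_that("parameters are recovered under 1% peak-relative noise", {
  p <- arrhenius_params(148.6, 319.0, 250)
  pk <- max(gen_thermogram(p, seed = 1)$Cp_ex)
  res <- vapply(1:30, function(s) {
    fit <- fit_thermogram(gen_thermogram(p, noise_abs = 0.01 * pk, seed = s))
    c(fit$params$E_A, fit$params$T_star)
  }, numeric(2))
  expect_lt(abs(median(res[1, ]) - 148.6) / 148.6, 0.01)
  expect_lt(abs(median(res[2, ]) - 319.0), 0.05)
})

test_that("Eyring derivations reproduce the published activation table", {
  ## columns: E_A, T* (Arrhenius table) -> dH, dS, dG (Eyring table, 25 C)
  tbl <- list(
    apo = list(EA = 111.1, Ts = 315.6, dH = 110.5, dS = 291.1, dG = 23.6),
    Ca  = list(EA = 148.6, Ts = 319.0, dH = 148.0, dS = 405.1, dG = 27.2),
    Mn  = list(EA = 191.1, Ts = 320.6, dH = 190.5, dS = 535.6, dG = 30.8),
    Mg  = list(EA = 198.4, Ts = 320.3, dH = 197.8, dS = 558.7, dG = 31.2))
  for (cond in tbl) {
    p <- arrhenius_params(cond$EA, cond$Ts, 100)
    ey <- eyring_parameters(p, T_ref = 298.15, rate_unit = "per_second")
    expect_lt(abs(ey$dH_act - cond$dH), 0.05)
    expect_lt(abs(ey$dS_act - cond$dS), 0.5)
    expect_lt(abs(ey$dG_act - cond$dG), 0.15)
    ## exact thermodynamic identity
    expect_equal(ey$dG_act, ey$dH_act - 298.15 * ey$dS_act / 1000,
                 tolerance = 1e-12)
    ## Arrhenius convention is untouched by the Eyring unit choice
    expect_equal(rate_constant(p, p$T_star), 1.0)
  }

  ## per-minute convention lowers dS by R ln 60
  p <- arrhenius_params(111.1, 315.6, 100)
  s_sec <- eyring_parameters(p, rate_unit = "per_second")$dS_act
  s_min <- eyring_parameters(p, rate_unit = "per_minute")$dS_act
  expect_equal(s_sec - s_min, 1000 * R_kcal * log(60), tolerance = 1e-9)
})

test_that("linear baseline subtraction restores the clean transition", {
  ## flanks must carry negligible transition signal; at 288 K the rate
  ## constant (hence Cp_ex) is ~1e-7 of the peak
  p <- arrhenius_params(111.1, 315.6, 250)
  grid <- seq(280, 330, by = 0.1)
  clean <- excess_heat_capacity(p, grid, 1)
  dirty <- gen_thermogram(p, grid = grid, baseline = c(0.02, -5), seed = 1)
  fixed <- subtract_baseline(dirty, pre_range = c(280, 288),
                             post_range = c(326, 330))
  expect_lt(max(abs(fixed$Cp_ex - clean$Cp_ex)), 2e-4)
  expect_lt(abs(pracma::trapz(fixed$T, fixed$Cp_ex) - 250) / 250, 0.005)
})
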