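# Two-compartment nutrient-coupled logistic model: rates, RK4, trajectories.

test_that("growth rate and carrying capacity are proportional to nutrient", {
  p <- population_params(mu_max = 0.8, K_max = 1e8, c_ref = 1)
  expect_identical(growth_rate(0, p), 0)
  expect_equal(growth_rate(p$c_ref, p), p$mu_max)
  expect_equal(growth_rate(0.5, p), 0.4)
  expect_identical(carrying_capacity(0, p), 0)
  expect_equal(carrying_capacity(p$c_ref, p), p$K_max)
  expect_equal(carrying_capacity(2, p), 2e8)
  expect_error(growth_rate(-0.1, p), ">= 0")
  expect_error(carrying_capacity(-1, p), ">= 0")
})

test_that("rhs matches the hand-computed four-vector and its limits", {
  p <- population_params(mu_max = 0.8, K_max = 1, c_ref = 1, beta = 1,
                         delta = 0.01, k_plus = 1, k_minus = 1e-3, D_n = 1)
  d <- ode_rhs(system_state(rho_b = 0.1, rho_p = 0.1, c_b = 1, c_p = 1), p)
  # frozen values computed by hand from the four expressions:
  # d rho_b = 0.8*0.1*0.9 + 0.1 - 1e-4; d rho_p = 0.072 - 0.1 + 1e-4
  expect_equal(unname(d), c(0.1719, -0.0279, -0.09, -0.09), tolerance = 1e-12)

  # empty system: nutrients only degrade and diffuse
  d0 <- ode_rhs(system_state(rho_b = 0, rho_p = 0, c_b = 0.8, c_p = 0.4), p)
  expect_equal(unname(d0[c("rho_b", "rho_p")]), c(0, 0))
  expect_equal(d0[["c_b"]], -0.01 * 0.8 + 1 * (0.4 - 0.8))
  expect_equal(d0[["c_p"]], -0.01 * 0.4 - 1 * (0.4 - 0.8))

  # starvation: the quadratic death term survives the c -> 0 limit
  ps <- population_params(mu_max = 0.8, K_max = 2, k_plus = 0, k_minus = 0,
                          D_n = 0, delta = 0, beta = 1)
  ds <- ode_rhs(system_state(rho_b = 0.5, rho_p = 0, c_b = 0, c_p = 0), ps)
  expect_equal(ds[["rho_b"]], -(0.8 / 2) * 0.25)
  expect_lte(ds[["rho_b"]], 0)

  expect_error(ode_rhs(c(rho_b = NaN, rho_p = 0, c_b = 1, c_p = 1), p),
               "non-finite")
})

test_that("rk4_step reproduces the symbolic linear-decay stage expansion", {
  # embed dy/dt = -y in the nutrient equation: delta = 1, everything else off
  p <- population_params(mu_max = 0, K_max = 1, k_plus = 0, k_minus = 0,
                         D_n = 0, delta = 1, beta = 0)
  s1 <- rk4_step(system_state(rho_b = 0, rho_p = 0, c_b = 1, c_p = 0), p, 0.1)
  h <- 0.1  # y1 = y0 (1 - h + h^2/2 - h^3/6 + h^4/24)
  expect_equal(s1[["c_b"]], 1 - h + h^2 / 2 - h^3 / 6 + h^4 / 24,
               tolerance = 1e-14)
  expect_equal(s1[["c_b"]], 0.90483750, tolerance = 1e-8)
  expect_equal(abs(s1[["c_b"]] - exp(-0.1)) < 1e-7, TRUE)

  # all rates zero: fixed point
  p0 <- population_params(mu_max = 0, K_max = 1, k_plus = 0, k_minus = 0,
                          D_n = 0, delta = 0, beta = 0)
  s <- system_state(rho_b = 0.3, rho_p = 0.2, c_b = 0.5, c_p = 0.1)
  s2 <- rk4_step(s, p0, 0.5)
  expect_equal(unclass(s2)[1:4], unclass(s)[1:4])
  expect_equal(s2[["t"]], 0.5)
  expect_error(rk4_step(s, p0, -1), "dt")
})

test_that("compiled integrator agrees with stepwise R composition", {
  p <- preset_params("shaking")
  tr <- simulate_population(p, initial = system_state(), t_end = 0.5, dt = 0.01)
  s <- system_state()
  for (i in 1:50) s <- rk4_step(s, p, 0.01)
  expect_equal(unname(unlist(tr[51, c("rho_b", "rho_p", "c_b", "c_p")])),
               unname(unclass(s)[1:4]), tolerance = 1e-12)
})

test_that("decoupled single-compartment limit matches the logistic closed form", {
  mu <- 0.9; K <- 5; rho0 <- 0.01
  p <- population_params(mu_max = mu, K_max = K, k_plus = 0, k_minus = 0,
                         D_n = 0, delta = 0, beta = 0, c_ref = 1)
  tr <- simulate_population(p, initial = system_state(rho_b = rho0, rho_p = 0,
                                                      c_b = 1, c_p = 1),
                            t_end = 20, dt = 0.01)
  exact <- K / (1 + (K / rho0 - 1) * exp(-mu * tr$time_h))
  expect_lt(max(abs(tr$rho_b - exact) / exact), 1e-6)
  expect_equal(tr$rho_p, rep(0, nrow(tr)))
})

test_that("with beta = 0 nutrients decay exponentially at rate delta", {
  p <- population_params(delta = 0.2, beta = 0, k_plus = 1, k_minus = 0.5,
                         D_n = 0.7)
  tr <- simulate_population(p, initial = system_state(rho_b = 0.1, rho_p = 0.1,
                                                      c_b = 0.6, c_p = 0.6),
                            t_end = 10, dt = 0.01)
  expect_equal(tr$c_b, 0.6 * exp(-0.2 * tr$time_h), tolerance = 1e-9)
  expect_equal(tr$c_p, 0.6 * exp(-0.2 * tr$time_h), tolerance = 1e-9)
})

test_that("pure exchange conserves cells; pure diffusion conserves nutrient", {
  p <- population_params(mu_max = 0, beta = 0, delta = 0,
                         k_plus = 0.8, k_minus = 0.3, D_n = 1.5)
  tr <- simulate_population(p, initial = system_state(rho_b = 0.2, rho_p = 0.7,
                                                      c_b = 0.9, c_p = 0.1),
                            t_end = 24, dt = 0.01)
  expect_lt(max(abs(tr$rho_b + tr$rho_p - 0.9)), 1e-10)
  expect_lt(max(abs(tr$c_b + tr$c_p - 1.0)), 1e-10)
})

test_that("presets carry the printed transport rates and share the rest", {
  sh <- preset_params("shaking")
  st <- preset_params("static")
  expect_equal(c(sh$k_plus, sh$D_n, sh$k_minus), c(1, 1, 0.001))
  expect_equal(c(st$k_plus, st$D_n, st$k_minus), c(0.025, 0.05, 1))
  shared <- setdiff(names(sh), c("k_plus", "k_minus", "D_n"))
  expect_identical(sh[shared], st[shared])
  expect_error(preset_params("vortex"), "shaking|static")
})

test_that("both presets show growth-saturation-decay with a single peak and total nutrient never increases", {
  peaks <- vapply(c("shaking", "static"), function(cond) {
    tr <- simulate_population(preset_params(cond), t_end = 120, dt = 0.02,
                              condition = cond)
    i <- which.max(tr$rho_b)
    expect_gt(tr$time_h[i], 0)
    expect_lt(tr$time_h[i], 120)
    # monotone rise to the unique global maximum, decline after it
    expect_gte(min(diff(tr$rho_b[1:i])), -1e-12)
    expect_lt(tr$rho_b[nrow(tr)], 0.6 * tr$rho_b[i])
    expect_lte(max(diff(tr$c_b + tr$c_p)), 0)
    tr$rho_b[i]
  }, numeric(1))
  expect_gt(peaks[["shaking"]], peaks[["static"]])
})
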