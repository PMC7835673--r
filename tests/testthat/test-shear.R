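# DPD bacteria-polymer-solvent network under oscillatory shear.
# Systems are deliberately small (L = 5, 375 beads) to keep the suite fast;
# the statistical assertions use crosslink counts whose signal clearly
# exceeds the stress noise at this size.

small_system <- function(condition = "shaking", seed = 3, ...)
  build_shear_system(condition, L = 5, seed = seed, ...)

test_that("composition matches the measured biovolume ratios and builds are deterministic", {
  sh <- small_system("shaking")
  st <- small_system("static")
  expect_equal(unname(sh$composition[["bacteria"]]), 0.53, tolerance = 0.03)
  expect_equal(unname(st$composition[["bacteria"]]), 0.72, tolerance = 0.03)
  expect_equal(sum(sh$composition), 1)
  expect_setequal(unique(sh$type), c(0L, 1L, 2L))

  sh2 <- small_system("shaking")
  expect_identical(sh$pos, sh2$pos)
  expect_identical(sh$vel, sh2$vel)

  expect_error(build_shear_system("static", L = 5, non_solvent_frac = 1.1),
               "infeasible")
  expect_error(build_shear_system("static", L = 30), "desk-scale")
})

test_that("crosslinking bookkeeping is exact and links join distinct non-solvent molecules", {
  sys <- small_system()
  expect_identical(add_crosslinks(sys, 0)$crosslinks, sys$crosslinks)
  linked <- add_crosslinks(sys, 40, seed = 7)
  expect_equal(nrow(linked$crosslinks), 40)
  i <- linked$crosslinks[, 1]; j <- linked$crosslinks[, 2]
  expect_true(all(linked$type[i] != 0L & linked$type[j] != 0L))
  expect_true(all(linked$mol[i] != linked$mol[j]))
  key <- paste(pmin(i, j), pmax(i, j))
  expect_false(any(duplicated(key)))

  expect_error(add_crosslinks(sys, 1e5, seed = 7), "cannot place")
})

test_that("crosslinks immobilise the polymer network", {
  sys <- small_system()
  disp2 <- vapply(c(0, 120, 400), function(nl) {
    s <- if (nl > 0) add_crosslinks(sys, nl, seed = 5) else sys
    poly <- s$type == 1L
    before <- s$pos[poly, , drop = FALSE]
    s2 <- biofilmadapt:::run_dpd(s, 400, record_every = 0)
    d <- (s2$pos[poly, ] - before) %% s$L
    d <- pmin(d, s$L - d)  # minimum-image displacement
    mean(rowSums(d^2))
  }, numeric(1))
  expect_true(all(diff(disp2) < 0))
})

test_that("momentum is conserved exactly and the thermostat needs fluctuation-dissipation", {
  sys <- small_system()
  mom0 <- colSums(sys$vel)
  s2 <- biofilmadapt:::run_dpd(sys, 300, record_every = 10)
  expect_lt(max(abs(colSums(s2$vel) - mom0)), 1e-10)
  expect_equal(mean(s2$last_record$temperature), 1, tolerance = 0.05)

  # negative control: random force stronger than fluctuation-dissipation
  hot <- small_system(params = dpd_params(sigma_r = 2 * sqrt(2 * 4.5)),
                      equil_steps = 0)
  h2 <- biofilmadapt:::run_dpd(hot, 300, record_every = 10)
  expect_gt(mean(tail(h2$last_record$temperature, 10)), 1.2)
})

test_that("the undriven and near-solvent systems respond like a fluid", {
  sys <- small_system()
  rec0 <- oscillate(sys, shear_protocol(0, 0.2, 3), seed = 2)
  expect_equal(mean(rec0$sigma_xy), 0, tolerance = 0.05)
  proj <- 2 * mean(rec0$sigma_xy * sin(0.2 * rec0$time))
  expect_equal(proj, 0, tolerance = 0.05)

  solv <- small_system(non_solvent_frac = 0.02)
  sr <- stress_response(oscillate(solv, shear_protocol(0.3, 0.2, 6),
                                  seed = 2))
  expect_gt(sr$G_double_prime, 0.05)
  expect_gt(sr$G_double_prime, 3 * abs(sr$G_prime))
})

test_that("the crosslinked network has a linear regime and stiffens beyond it", {
  sys <- add_crosslinks(small_system(), 250, seed = 5)
  resp <- vapply(c(0.1, 0.2, 1.2), function(g0) {
    stress_response(oscillate(sys, shear_protocol(g0, 0.2, 6),
                              seed = 11))$amplitude / g0
  }, numeric(1))
  # doubling the amplitude inside the linear regime doubles the stress
  expect_equal(resp[2] / resp[1], 1, tolerance = 0.15)
  # geometric hardening: clear departure from linearity at large amplitude
  expect_gt(resp[3] / mean(resp[1:2]), 1.3)
})

test_that("the stress-response ratio is 1 for self-comparison and grows with crosslink ratio", {
  st <- small_system("static", seed = 4)
  self <- stress_ratio_curve(st, st, crosslink_ratios = 1,
                             n_static_links = 60, amplitudes = 0.2,
                             omega = 0.2, n_cycles = 4, seed = 6)
  expect_false(self$failed)
  expect_equal(self$stress_ratio, 1, tolerance = 1e-9)

  sh <- small_system("shaking", seed = 4)
  tab <- stress_ratio_curve(st, sh, crosslink_ratios = c(1.5, 5),
                            n_static_links = 60, amplitudes = 0.2,
                            omega = 0.2, n_cycles = 6, seed = 6)
  expect_false(any(tab$failed))
  expect_true(all(diff(tab$stress_ratio) > 0))
})

test_that("a quadratic fit of a synthesised ratio table recovers its generator, and the published curve evaluates correctly", {
  x <- seq(1, 12, by = 0.5)
  y <- 0.6 * x^2 + 2 * x - 0.5
  fit <- lm(y ~ x + I(x^2))
  expect_equal(unname(coef(fit)), c(-0.5, 2, 0.6), tolerance = 1e-8)

  expect_equal(evaluate_master_curve(0), -1.14)
  expect_equal(evaluate_master_curve(6), 52.26)
  expect_equal(evaluate_master_curve(12), 159.66)
  expect_error(evaluate_master_curve(-1), ">= 0")
})
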