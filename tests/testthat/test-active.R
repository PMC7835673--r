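# Run-and-tumble colony simulator: motion, forces, growth, MSD.

no_tumble_cfg <- function(...) active_config(tau_run = 1e7, dt = 0.05, ...)

test_that("an isolated bacterium runs ballistically between tumbles", {
  cfg <- no_tumble_cfg()
  col <- new_colony(cfg, 1)
  col$theta <- 0.7
  out <- step_colony(col, cfg, n_steps = 100, grow = FALSE, seed = 1)
  d <- sqrt((out$x - col$x)^2 + (out$y - col$y)^2)
  expect_equal(d, cfg$v * cfg$dt * 100, tolerance = 1e-9)
  expect_equal(atan2(out$y - col$y, out$x - col$x), 0.7, tolerance = 1e-12)
})

test_that("pair forces vanish beyond the cutoff and at the potential minimum", {
  cfg <- no_tumble_cfg(v = 0)
  # far pair: no displacement at all
  col <- new_colony(cfg, 2, positions = cbind(c(50, 150), c(50, 50)),
                    thetas = c(0, 0))
  out <- step_colony(col, cfg, n_steps = 5, grow = FALSE, seed = 1)
  expect_equal(out$x, col$x)
  expect_equal(out$y, col$y)

  # numeric root of the radial force law is the zero-force separation
  r_star <- uniroot(split_lj_force, c(0.81, 1.2), epsilon = cfg$epsilon,
                    sigma = cfg$w, lambda = cfg$attraction_strength,
                    tol = 1e-12)$root
  expect_equal(r_star, 2^(1 / 6) * cfg$w, tolerance = 1e-6)
  # two parallel rods side by side at that separation: zero net force
  col <- new_colony(cfg, 2, positions = cbind(c(50, 50), c(50, 50 + r_star)),
                    thetas = c(0, 0))
  out <- step_colony(col, cfg, n_steps = 1, grow = FALSE, seed = 1)
  expect_equal(out$y, col$y, tolerance = 1e-7)
  # slightly closer: repulsion separates them
  col2 <- col; col2$y[2] <- col$y[1] + 0.9 * r_star
  out2 <- step_colony(col2, cfg, n_steps = 1, grow = FALSE, seed = 1)
  expect_gt(out2$y[2] - out2$y[1], 0.9 * r_star)
  # slightly beyond: the attractive well pulls them together
  col3 <- col; col3$y[2] <- col$y[1] + 1.3 * r_star
  out3 <- step_colony(col3, cfg, n_steps = 1, grow = FALSE, seed = 1)
  expect_lt(out3$y[2] - out3$y[1], 1.3 * r_star)
})

test_that("growth is linear and division conserves body length", {
  cfg <- active_config(div_angle_sd = 0)
  col <- new_colony(cfg, 1)
  # half a duplication time: half the birth length has been added
  g <- grow_and_divide(col, cfg, dt_h = 0.5)
  expect_equal(g$length, 1.5 * cfg$l0)
  # at t_dup the mother reaches 2 l0 and splits into two birth-length cells
  g2 <- grow_and_divide(g, cfg, dt_h = 0.5)
  expect_equal(nrow(g2), 2)
  expect_equal(g2$length, rep(cfg$l0, 2))
  expect_equal(sum(g2$length), 2 * cfg$l0)  # continuous total length
  expect_equal(g2$parent, rep(col$id, 2))
  # daughters sit end to end along the mother axis
  expect_equal(sqrt(diff(g2$x)^2 + diff(g2$y)^2), cfg$l0)

  # three duplication times: 2^3 cells, in R and in the compiled engine
  col8 <- col
  for (k in 1:6) col8 <- grow_and_divide(col8, cfg, dt_h = 0.5)
  expect_equal(nrow(col8), 8)
  tr <- simulate_colony(cfg, hours = 3.001, n0 = 1, seed = 4)
  expect_equal(nrow(tr$frames[[length(tr$frames)]]), 8)
})

test_that("counts are non-decreasing, follow 2^t, and the fitted doubling time is 1 h", {
  tr <- simulate_colony(active_config(), hours = 4.01, n0 = 1,
                        save_every_s = 600, seed = 9)
  gc <- growth_curve(tr)
  expect_true(all(diff(gc$n) >= 0))
  expect_equal(gc$n[length(gc$n)], 16)  # 2^4 from one cell
  expect_equal(attr(gc, "doubling_time_h"), 1, tolerance = 0.05)
})

test_that("identical seed and configuration reproduce the trajectory bit for bit", {
  cfg <- active_config()
  t1 <- simulate_colony(cfg, hours = 0.2, n0 = 4, seed = 123)
  t2 <- simulate_colony(cfg, hours = 0.2, n0 = 4, seed = 123)
  expect_identical(t1$frames, t2$frames)
  t3 <- simulate_colony(cfg, hours = 0.2, n0 = 4, seed = 124)
  expect_false(identical(t1$frames, t3$frames))
})

test_that("MSD crosses over from ballistic to diffusive scaling", {
  cfg <- active_config()
  trs <- lapply(1:10, function(s)
    simulate_colony(cfg, hours = 5000 / 3600, n0 = 1, grow = FALSE,
                    save_every_s = 0.5, seed = 300 + s))
  m <- colony_msd(trs[[1]])
  msd <- rowMeans(vapply(trs, function(tr) colony_msd(tr)$msd,
                         numeric(nrow(m))))
  # log-log slopes: ~2 well below tau_run, ~1 well above
  bal <- m$lag_s < cfg$tau_run / 5
  dif <- m$lag_s > 5 * cfg$tau_run
  slope <- function(sel) coef(lm(log(msd[sel]) ~ log(m$lag_s[sel])))[[2]]
  expect_equal(slope(bal), 2, tolerance = 0.1)
  expect_equal(slope(dif), 1, tolerance = 0.25)

  est <- estimate_diffusion(trs)
  expect_equal(est$D, cfg$v^2 * cfg$tau_run / 2, tolerance = 0.3)
  expect_gt(est$crossover_s, 0)

  # immobile bacterium: no displacement at all
  cfg0 <- active_config(v = 0)
  tr0 <- simulate_colony(cfg0, hours = 0.25, n0 = 1, grow = FALSE,
                         save_every_s = 5, seed = 1)
  expect_equal(estimate_diffusion(tr0)$D, 0, tolerance = 1e-12)

  short <- simulate_colony(cfg, hours = 0.05, n0 = 1, grow = FALSE,
                           save_every_s = 1, seed = 1)
  expect_error(estimate_diffusion(short), "insufficient sampling")
})

test_that("an unresolvable deep overlap raises a timestep error", {
  cfg <- active_config(mobility = 0, v = 0)  # forces cannot relax anything
  col <- new_colony(cfg, 2, positions = cbind(c(50, 50.1), c(50, 50)),
                    thetas = c(0, 0))
  expect_error(step_colony(col, cfg, n_steps = 200, grow = FALSE, seed = 1),
               "timestep too large")
})

test_that("colony frames round-trip through the long CSV format", {
  tr <- simulate_colony(active_config(), hours = 0.05, n0 = 3,
                        save_every_s = 60, seed = 5)
  path <- tempfile(fileext = ".csv")
  write_colony(tr, path)
  long <- read_colony(path)
  expect_equal(sort(unique(long$frame)), seq_along(tr$frames) - 1)
  f0 <- long[long$frame == 0, ]
  expect_equal(f0$x_um, tr$frames[[1]]$x)
  expect_equal(f0$length_um, tr$frames[[1]]$length)
})
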