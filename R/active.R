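#' Configuration of the 2D run-and-tumble colony simulator
#'
#' Growing, dividing, weakly attracting rod-shaped (spherocylindrical)
#' bacteria in a periodic 2D box. An isolated cell runs at speed \code{v}
#' and tumbles as a Poisson process with mean run time \code{tau_run},
#' redrawing its orientation uniformly; the defaults \code{v = 0.2} um/s
#' and \code{tau_run = 2 D / v^2 = 35} s make the long-time diffusion
#' coefficient \eqn{D = v^2 \tau/2 = 0.7} um^2/s, the published
#' calibration pair. Cells elongate linearly from birth length \code{l0}
#' to \code{2 l0} over \code{t_dup} (1 h) and then split into two
#' daughters placed end to end with a small orientation perturbation.
#' Pairs interact through a split Lennard-Jones potential on the minimum
#' distance between their body segments: full-strength repulsion
#' (energy scale \code{epsilon}) continued by an attractive well of depth
#' \code{attraction_strength * epsilon} (default 0.2, the
#' polymer-depletion attraction).
#'
#' @param v self-propulsion speed (um/s).
#' @param tau_run mean run duration between tumbles (s).
#' @param epsilon repulsion energy scale (arbitrary units).
#' @param attraction_strength well depth as a fraction of \code{epsilon}.
#' @param t_dup mean duplication time (h).
#' @param l0 birth length (um); rod width \code{w} (um). Defaults 2 and
#'   0.8 um, typical of \emph{Pseudomonas}-sized rods.
#' @param w rod width/diameter (um).
#' @param dt timestep (s); must be much smaller than \code{tau_run}.
#' @param box periodic square box side (um).
#' @param mobility translational mobility (um^2 per unit energy per s)
#'   multiplying interaction forces in the overdamped update.
#' @param div_angle_sd sd (rad) of the daughter orientation noise.
#' @param growth_cv coefficient of variation of the per-cell duplication
#'   time (0 = the deterministic division rule).
#' @param max_step cap (um) on the per-step displacement, a stabilising
#'   guard against force spikes right after divisions.
#' @return An object of class \code{"active_config"}.
#' @export
active_config <- function(v = 0.2, tau_run = 35, epsilon = 1,
                          attraction_strength = 0.2, t_dup = 1,
                          l0 = 2, w = 0.8, dt = 0.05, box = 400,
                          mobility = 0.1, div_angle_sd = 0.1,
                          growth_cv = 0, max_step = 0.2) {
  stopifnot(v >= 0, tau_run > 0, dt > 0, box > 0, l0 > 0, w > 0,
            epsilon >= 0, attraction_strength >= 0, t_dup > 0,
            mobility >= 0, growth_cv >= 0, max_step > 0)
  if (dt > tau_run / 10)
    stop("'dt' must be much smaller than 'tau_run' (dt <= tau_run/10)")
  structure(list(v = v, tau_run = tau_run, epsilon = epsilon,
                 attraction_strength = attraction_strength, t_dup = t_dup,
                 l0 = l0, w = w, dt = dt, box = box, mobility = mobility,
                 div_angle_sd = div_angle_sd, growth_cv = growth_cv,
                 max_step = max_step),
            class = "active_config")
}

#' Create an initial colony frame
#'
#' Builds the data frame of cell states the simulator consumes: by default
#' \code{n0} birth-length cells on a sparse grid with orientation 0.
#'
#' @param config an \code{\link{active_config}}.
#' @param n0 number of cells.
#' @param positions optional n x 2 matrix of positions (um).
#' @param thetas,lengths optional orientations (rad) and body lengths (um).
#' @return A colony data frame (columns \code{x, y, theta, length, age_h,
#'   id, parent, inv_tdup_h}).
#' @export
new_colony <- function(config, n0 = 1, positions = NULL, thetas = NULL,
                       lengths = NULL) {
  if (is.null(positions)) {
    side <- max(1, ceiling(sqrt(n0)))
    sp <- config$box / side
    idx <- seq_len(n0) - 1
    positions <- cbind((idx %% side + 0.5) * sp,
                       (idx %/% side + 0.5) * sp)
  }
  if (is.null(thetas)) thetas <- rep(0, n0)
  if (is.null(lengths)) lengths <- rep(config$l0, n0)
  df <- data.frame(x = positions[, 1], y = positions[, 2], theta = thetas,
                   length = lengths, age_h = 0, id = seq_len(n0),
                   parent = 0L, inv_tdup_h = 0)
  df
}

colony_matrix <- function(df)
  as.matrix(df[, c("x", "y", "theta", "length", "age_h", "id", "parent",
                   "inv_tdup_h")])

frame_df <- function(m) {
  df <- as.data.frame(m)
  names(df) <- c("x", "y", "theta", "length", "age_h", "id", "parent",
                 "inv_tdup_h")
  df
}

#' Simulate a growing colony
#'
#' Runs the agent-based model for \code{hours} of simulated time from
#' \code{n0} seed cells (or a user-supplied colony frame). Identical seed
#' and configuration give a bit-identical trajectory.
#'
#' @param config an \code{\link{active_config}}.
#' @param hours simulated duration (h).
#' @param n0 number of initial cells (ignored when \code{colony} given).
#' @param colony optional starting colony data frame (a trajectory frame).
#' @param save_every_s interval between saved frames (s).
#' @param grow enable growth and division.
#' @param move enable motility and interactions.
#' @param seed integer RNG seed.
#' @return A \code{"colony_trajectory"}: list with \code{frames} (data
#'   frames with columns x, y, theta, length, age_h, id, parent),
#'   \code{times_s} and \code{config}.
#' @examples
#' tr <- simulate_colony(active_config(), hours = 2, seed = 1)
#' growth_curve(tr)
#' @export
simulate_colony <- function(config, hours, n0 = 1, colony = NULL,
                            save_every_s = 60, grow = TRUE, move = TRUE,
                            seed = 1) {
  stopifnot(inherits(config, "active_config"), hours > 0)
  if (is.null(colony)) colony <- new_colony(config, n0)
  n_steps <- round(hours * 3600 / config$dt)
  save_every <- max(1L, round(save_every_s / config$dt))
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(seed)
  res <- colony_run_cpp(colony_matrix(colony), unclass(config), n_steps,
                        save_every, grow, move)
  structure(list(frames = lapply(res$frames, frame_df),
                 times_s = res$times_s, config = config, seed = seed),
            class = "colony_trajectory")
}

#' @export
print.colony_trajectory <- function(x, ...) {
  n0 <- nrow(x$frames[[1]])
  nf <- length(x$frames)
  cat(sprintf("Colony trajectory: %d frames over %.2f h, %d -> %d cells\n",
              nf, max(x$times_s) / 3600, n0, nrow(x$frames[[nf]])))
  invisible(x)
}

#' Advance a colony by discrete simulation steps
#'
#' One (or more) timesteps of the full dynamics: run-and-tumble motion,
#' pairwise forces, growth and division.
#'
#' @param colony a colony data frame (e.g. a frame of
#'   \code{\link{simulate_colony}} or \code{\link{new_colony}} output).
#' @param config an \code{\link{active_config}}.
#' @param n_steps number of timesteps.
#' @param grow,move enable growth/motility.
#' @param seed integer RNG seed.
#' @return The advanced colony data frame.
#' @export
step_colony <- function(colony, config, n_steps = 1, grow = TRUE,
                        move = TRUE, seed = 1) {
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(seed)
  res <- colony_run_cpp(colony_matrix(colony), unclass(config), n_steps,
                        0L, grow, move)
  frame_df(res$frames[[length(res$frames)]])
}

#' Apply the growth and division rule alone
#'
#' Reference (pure R) implementation of elongation and binary division
#' over one interval \code{dt_h}, without motion or forces: length grows
#' linearly at \code{l0/t_dup}; a cell reaching \code{2 l0} is replaced by
#' two end-to-end daughters of length \code{l0} whose orientations are the
#' mother's plus Gaussian noise.
#'
#' @param colony a colony data frame.
#' @param config an \code{\link{active_config}}.
#' @param dt_h time increment (h).
#' @return The updated colony data frame.
#' @export
grow_and_divide <- function(colony, config, dt_h) {
  colony$inv_tdup_h[colony$inv_tdup_h <= 0] <- 1 / config$t_dup
  colony$length <- colony$length + config$l0 * colony$inv_tdup_h * dt_h
  colony$age_h <- colony$age_h + dt_h
  next_id <- max(colony$id) + 1L
  out <- vector("list", nrow(colony))
  for (i in seq_len(nrow(colony))) {
    ci <- colony[i, ]
    if (ci$length >= 2 * config$l0) {
      u <- c(cos(ci$theta), sin(ci$theta))
      noise <- if (config$div_angle_sd > 0)
        stats::rnorm(2, 0, config$div_angle_sd) else c(0, 0)
      out[[i]] <- data.frame(
        x = ci$x + c(1, -1) * u[1] * config$l0 / 2,
        y = ci$y + c(1, -1) * u[2] * config$l0 / 2,
        theta = ci$theta + noise, length = config$l0, age_h = 0,
        id = c(next_id, next_id + 1L), parent = ci$id,
        inv_tdup_h = 1 / config$t_dup)
      next_id <- next_id + 2L
    } else out[[i]] <- ci
  }
  do.call(rbind, out)
}

#' Cell counts along a colony trajectory
#'
#' @param trajectory a \code{"colony_trajectory"}.
#' @return Data frame with \code{time_s}, \code{time_h} and \code{n};
#'   attribute \code{doubling_time_h} holds the fitted doubling time (see
#'   \code{\link{doubling_time}}).
#' @export
growth_curve <- function(trajectory) {
  stopifnot(inherits(trajectory, "colony_trajectory"))
  if (length(trajectory$frames) < 2) stop("need at least 2 frames")
  n <- vapply(trajectory$frames, nrow, integer(1))
  out <- data.frame(time_s = trajectory$times_s,
                    time_h = trajectory$times_s / 3600, n = n)
  attr(out, "doubling_time_h") <- doubling_time(out)
  out
}

#' Doubling time from a count curve
#'
#' Least-squares slope of log2 N versus time; in the dilute regime the
#' inverse slope equals the configured duplication time.
#'
#' @param counts data frame with \code{time_h} and \code{n} (e.g. from
#'   \code{\link{growth_curve}}).
#' @return Doubling time in hours.
#' @export
doubling_time <- function(counts) {
  stopifnot(all(c("time_h", "n") %in% names(counts)))
  fit <- stats::lm(log2(n) ~ time_h, data = counts)
  1 / unname(stats::coef(fit)[2])
}

#' Split Lennard-Jones pair force law
#'
#' Radial force (positive = repulsive) used between bacterial body
#' segments: the full-strength Lennard-Jones repulsion for
#' \eqn{r \le 2^{1/6}\sigma} continued by the attractive branch scaled by
#' \code{lambda}, giving a well of depth \code{lambda * epsilon}. The
#' force is zero beyond \code{2.5 sigma} and at the potential minimum
#' \eqn{r = 2^{1/6}\sigma}.
#'
#' @param r separation(s), same units as \code{sigma}.
#' @param epsilon energy scale.
#' @param sigma length scale (the rod width).
#' @param lambda attractive-branch scaling (well depth fraction).
#' @return Force magnitude(s); positive values push the pair apart.
#' @export
split_lj_force <- function(r, epsilon = 1, sigma = 0.8, lambda = 0.2) {
  stopifnot(all(r > 0))
  s6 <- (sigma / r)^6
  f <- 24 * epsilon * s6 * (2 * s6 - 1) / r
  f[r > 2^(1 / 6) * sigma] <- lambda * f[r > 2^(1 / 6) * sigma]
  f[r >= 2.5 * sigma] <- 0
  f
}

#' Mean-squared displacement of tracked cells
#'
#' Time-averaged MSD over all frame origins at the requested lags,
#' using unwrapped coordinates (the simulator never wraps positions; the
#' periodic images enter only through the forces).
#'
#' @param trajectory a \code{"colony_trajectory"} with constant cell count
#'   (growth disabled).
#' @param lags_s lag times (s); default a log-spaced set spanning the
#'   ballistic-to-diffusive crossover.
#' @return Data frame with \code{lag_s} and \code{msd} (um^2).
#' @export
colony_msd <- function(trajectory, lags_s = NULL) {
  stopifnot(inherits(trajectory, "colony_trajectory"))
  times <- trajectory$times_s
  dt_f <- diff(times[1:2])
  n_fr <- length(times)
  counts <- vapply(trajectory$frames, nrow, integer(1))
  if (length(unique(counts)) != 1)
    stop("MSD requires a constant number of cells (run with grow = FALSE)")
  if (is.null(lags_s))
    lags_s <- unique(round(exp(seq(log(dt_f), log(times[n_fr] / 4),
                                   length.out = 40)) / dt_f)) * dt_f
  xs <- vapply(trajectory$frames, function(f) f$x, numeric(counts[1]))
  ys <- vapply(trajectory$frames, function(f) f$y, numeric(counts[1]))
  xs <- matrix(xs, nrow = counts[1]); ys <- matrix(ys, nrow = counts[1])
  msd <- vapply(lags_s, function(L) {
    k <- round(L / dt_f)
    if (k < 1 || k >= n_fr) return(NA_real_)
    i0 <- seq_len(n_fr - k)
    mean((xs[, i0 + k, drop = FALSE] - xs[, i0, drop = FALSE])^2 +
         (ys[, i0 + k, drop = FALSE] - ys[, i0, drop = FALSE])^2)
  }, numeric(1))
  ok <- is.finite(msd)
  data.frame(lag_s = lags_s[ok], msd = msd[ok])
}

#' Long-time diffusion coefficient of a run-and-tumble cell
#'
#' Estimates \eqn{D} from the diffusive branch of the mean-squared
#' displacement, \eqn{MSD(\Delta t) \to 4 D \Delta t} in 2D (slope fitted
#' with a free intercept, which absorbs the finite persistence time), and
#' reports the ballistic-to-diffusive crossover time \eqn{4D/v^2}.
#' For complete orientation decorrelation the closed form is
#' \eqn{D = v^2 \tau_{run}/2}.
#'
#' @param trajectories a \code{"colony_trajectory"} (growth disabled) or a
#'   list of them; MSDs are averaged across trajectories and cells.
#' @param fit_range lag window (s) for the linear fit; default
#'   \code{[5 tau_run, T/4]}.
#' @return List of class \code{"diffusion_estimate"} with \code{D}
#'   (um^2/s), \code{crossover_s}, and the averaged \code{msd} table.
#' @export
estimate_diffusion <- function(trajectories, fit_range = NULL) {
  if (inherits(trajectories, "colony_trajectory"))
    trajectories <- list(trajectories)
  cfg <- trajectories[[1]]$config
  T_tot <- max(trajectories[[1]]$times_s)
  if (T_tot < 10 * cfg$tau_run)
    stop("insufficient sampling: trajectory spans ", T_tot,
         " s < 10 * tau_run = ", 10 * cfg$tau_run, " s")
  msds <- lapply(trajectories, colony_msd)
  lag <- msds[[1]]$lag_s
  msd <- rowMeans(vapply(msds, function(m) m$msd, numeric(length(lag))))
  if (is.null(fit_range)) fit_range <- c(5 * cfg$tau_run, T_tot / 4)
  sel <- lag >= fit_range[1] & lag <= fit_range[2]
  if (sum(sel) < 3) stop("insufficient sampling in the diffusive window")
  fit <- stats::lm(msd[sel] ~ lag[sel])
  D <- unname(stats::coef(fit)[2]) / 4
  structure(list(D = D, crossover_s = 4 * D / cfg$v^2,
                 msd = data.frame(lag_s = lag, msd = msd),
                 fit_range = fit_range),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("D_eff = %.4g um^2/s (ballistic-diffusive crossover ~ %.1f s)\n",
              x$D, x$crossover_s))
  invisible(x)
}

#' Write or read colony trajectory frames as CSV
#'
#' Long format: \code{frame,time_s,id,x_um,y_um,theta_rad,length_um}.
#'
#' @param trajectory a \code{"colony_trajectory"}.
#' @param path file path.
#' @return \code{path} (write); a data frame (read).
#' @export
write_colony <- function(trajectory, path) {
  frames <- trajectory$frames
  long <- do.call(rbind, lapply(seq_along(frames), function(k) {
    f <- frames[[k]]
    data.frame(frame = k - 1L, time_s = trajectory$times_s[k], id = f$id,
               x_um = f$x, y_um = f$y, theta_rad = f$theta,
               length_um = f$length)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed: %s", trajectory$seed), con)
  utils::write.csv(long, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_colony
#' @export
read_colony <- function(path) {
  utils::read.csv(path, comment.char = "#")
}
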