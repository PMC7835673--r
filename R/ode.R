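#' Nutrient-dependent specific growth rate
#'
#' Monod-type strict proportionality between the specific growth rate and
#' the limiting-nutrient concentration: \eqn{\mu(c) = \mu_{max} c/c_{ref}}.
#'
#' @param c nutrient concentration (>= 0); vectorised.
#' @param params a \code{\link{population_params}} object.
#' @return Specific growth rate(s) in 1/h.
#' @export
growth_rate <- function(c, params) {
  if (any(!is.finite(c)) || any(c < 0))
    stop("nutrient concentration must be finite and >= 0")
  params$mu_max * c / params$c_ref
}

#' Nutrient-dependent carrying capacity
#'
#' \eqn{K(c) = K_{max} c/c_{ref}}: the maximum sustainable population scales
#' with nutrient availability. In the logistic term the nutrient factor of
#' \eqn{\mu(c)/K(c)} cancels, so the quadratic death term stays finite at
#' \eqn{c = 0} (see \code{\link{ode_rhs}}).
#'
#' @inheritParams growth_rate
#' @return Carrying capacity in normalised cell-density units.
#' @export
carrying_capacity <- function(c, params) {
  if (any(!is.finite(c)) || any(c < 0))
    stop("nutrient concentration must be finite and >= 0")
  params$K_max * c / params$c_ref
}

#' Time derivative of the two-compartment system
#'
#' The four coupled equations. For each compartment the population follows a
#' logistic law whose rate and capacity are proportional to the local
#' nutrient, written in the cancellation form
#' \eqn{\mu(c)\rho - (\mu_{max}/K_{max})\rho^2} so that starvation
#' (\eqn{c = 0}) yields pure quadratic decay (death phase). Bacteria attach
#' (\code{k_plus}, plankton to biofilm) and detach (\code{k_minus}); nutrient
#' is consumed proportionally to growth (\code{beta}), self-degrades
#' (\code{delta}) and diffuses between compartments proportionally to the
#' concentration difference (\code{D_n}). In a closed batch the total
#' nutrient can only decrease.
#'
#' @param state a \code{\link{system_state}} or a numeric vector with named
#'   elements \code{rho_b, rho_p, c_b, c_p}.
#' @param params a \code{\link{population_params}} object.
#' @return Named numeric vector of derivatives
#'   \code{(rho_b, rho_p, c_b, c_p)} in units per hour.
#' @export
ode_rhs <- function(state, params) {
  s <- unclass(state)
  if (any(!is.finite(s[c("rho_b", "rho_p", "c_b", "c_p")])))
    stop("non-finite state component")
  rho_b <- s[["rho_b"]]; rho_p <- s[["rho_p"]]
  c_b <- s[["c_b"]]; c_p <- s[["c_p"]]
  death <- params$mu_max / params$K_max
  g_b <- growth_rate(c_b, params)
  g_p <- growth_rate(c_p, params)
  d_rho_b <- g_b * rho_b - death * rho_b^2 +
    params$k_plus * rho_p - params$k_minus * rho_b
  d_rho_p <- g_p * rho_p - death * rho_p^2 -
    params$k_plus * rho_p + params$k_minus * rho_b
  d_c_b <- -params$beta * g_b * rho_b - params$delta * c_b +
    params$D_n * (c_p - c_b)
  d_c_p <- -params$beta * g_p * rho_p - params$delta * c_p -
    params$D_n * (c_p - c_b)
  c(rho_b = d_rho_b, rho_p = d_rho_p, c_b = d_c_b, c_p = d_c_p)
}

#' One classical fourth-order Runge-Kutta step
#'
#' Advances the four-variable state by \code{dt} with the standard four-stage
#' scheme (local error \eqn{O(dt^5)}). Any component driven below zero by
#' the fixed step is clamped to zero (the integrator can undershoot near
#' extinction); clamping is reported via a warning from
#' \code{\link{simulate_population}}.
#'
#' @inheritParams ode_rhs
#' @param dt step size in hours (> 0).
#' @return A \code{\link{system_state}} at \code{t + dt}.
#' @export
rk4_step <- function(state, params, dt) {
  if (!is.numeric(dt) || dt <= 0) stop("'dt' must be > 0")
  s <- unclass(state)[c("rho_b", "rho_p", "c_b", "c_p")]
  f <- function(y) {
    y <- pmax(y, 0)  # rhs is defined on the physical orthant
    ode_rhs(c(y, t = 0), params)
  }
  k1 <- f(s)
  k2 <- f(s + dt / 2 * k1)
  k3 <- f(s + dt / 2 * k2)
  k4 <- f(s + dt * k3)
  out <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  out <- pmax(out, 0)
  system_state(out[["rho_b"]], out[["rho_p"]], out[["c_b"]], out[["c_p"]],
               t = unclass(state)[["t"]] + dt)
}

#' Integrate the two-compartment model on a uniform grid
#'
#' Fixed-step RK4 integration from \code{initial} to \code{t_end}. For the
#' default presets the biofilm density traverses the three observed regimes:
#' exponential growth, saturation, and nutrient-exhaustion decay.
#'
#' @param params a \code{\link{population_params}} object.
#' @param initial a \code{\link{system_state}}; the default starts with a
#'   dilute planktonic inoculum, an empty surface and fresh nutrient.
#' @param t_end final time (h).
#' @param dt step size (h); the default 0.01 h resolves the fastest rate
#'   (1 1/h) with 100 steps.
#' @param condition optional label stored with the trajectory.
#' @return A \code{"biofilm_trajectory"}: a data frame with columns
#'   \code{time_h, rho_b, rho_p, c_b, c_p} and attributes \code{params},
#'   \code{dt} and \code{condition}.
#' @examples
#' tr <- simulate_population(preset_params("shaking"), t_end = 96)
#' tr[which.max(tr$rho_b), ]
#' @export
simulate_population <- function(params, initial = system_state(),
                                t_end = 96, dt = 0.01, condition = NA_character_) {
  if (t_end <= 0) stop("'t_end' must be > 0")
  if (dt <= 0) stop("'dt' must be > 0")
  s0 <- unclass(initial)
  res <- rk4_integrate_cpp(
    c(s0[["rho_b"]], s0[["rho_p"]], s0[["c_b"]], s0[["c_p"]]),
    c(params$mu_max, params$K_max, params$k_plus, params$k_minus,
      params$D_n, params$delta, params$beta, params$c_ref),
    t_end, dt)
  if (res$clamped > 0)
    warning(sprintf("clamped %d negative component(s) to zero during integration",
                    res$clamped))
  m <- res$states
  if (any(!is.finite(m))) {
    bad <- which(!stats::complete.cases(is.finite(m)))[1]
    stop(sprintf("trajectory blew up (non-finite values) near t = %.3f h",
                 s0[["t"]] + (bad - 1) * dt))
  }
  out <- data.frame(time_h = s0[["t"]] + res$time,
                    rho_b = m[, 1], rho_p = m[, 2],
                    c_b = m[, 3], c_p = m[, 4])
  structure(out, params = params, dt = dt, condition = condition,
            class = c("biofilm_trajectory", "data.frame"))
}

#' @export
print.biofilm_trajectory <- function(x, ...) {
  cond <- attr(x, "condition")
  cat(sprintf("Biofilm population trajectory%s: %d points, t in [%g, %g] h (dt = %g h)\n",
              if (is.na(cond)) "" else paste0(" [", cond, "]"),
              nrow(x), min(x$time_h), max(x$time_h), attr(x, "dt")))
  pk <- x[which.max(x$rho_b), ]
  cat(sprintf("  peak rho_b = %.4g at t = %.2f h; final (rho_b, rho_p) = (%.4g, %.4g)\n",
              pk$rho_b, pk$time_h, x$rho_b[nrow(x)], x$rho_p[nrow(x)]))
  invisible(x)
}

#' @export
plot.biofilm_trajectory <- function(x, log = "y", ...) {
  pos <- x$rho_b > 0 | x$rho_p > 0
  ylim <- range(c(x$rho_b[x$rho_b > 0], x$rho_p[x$rho_p > 0]))
  plot(x$time_h, pmax(x$rho_b, ylim[1]), type = "l", lwd = 2, col = "darkgreen",
       log = log, xlab = "time (h)", ylab = "cell density (normalised)",
       ylim = ylim, ...)
  lines(x$time_h, pmax(x$rho_p, ylim[1]), col = "grey40")
  sc <- ylim[2]
  lines(x$time_h, pmax(x$c_b * sc, ylim[1]), col = "darkgreen", lty = 2)
  lines(x$time_h, pmax(x$c_p * sc, ylim[1]), col = "grey40", lty = 2)
  legend("bottomright", bty = "n", lty = c(1, 1, 2, 2), lwd = c(2, 1, 1, 1),
         col = c("darkgreen", "grey40", "darkgreen", "grey40"),
         legend = c("biofilm", "plankton", "nutrient (biofilm, scaled)",
                    "nutrient (plankton, scaled)"))
  invisible(x)
}
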