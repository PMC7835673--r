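#' Extract storage and loss moduli from an oscillatory stress record
#'
#' For a sinusoidal strain \eqn{\gamma(t) = \gamma_0 \sin(\omega t)} the
#' stress of a linear viscoelastic material is
#' \eqn{\sigma(t) = \gamma_0 [G' \sin(\omega t) + G'' \cos(\omega t)]}.
#' The moduli are recovered by Fourier projection over whole cycles:
#' \eqn{G' = 2\,\overline{\sigma(t)\sin(\omega t)}/\gamma_0} and
#' \eqn{G'' = 2\,\overline{\sigma(t)\cos(\omega t)}/\gamma_0}, and the
#' shear viscosity as \eqn{\eta = G''/\omega}. The strain amplitude is
#' measured from \code{gamma_t} by the same projection.
#'
#' @param sigma_t stress record (Pa), sampled uniformly in time.
#' @param gamma_t strain record, same sampling.
#' @param omega angular frequency (rad/s).
#' @param time time stamps (s); default a uniform grid starting at 0 is
#'   reconstructed from \code{dt}.
#' @param dt sampling interval (s) when \code{time} is not given.
#' @return An object of class \code{"viscoelastic_moduli"}: list with
#'   \code{G_prime}, \code{G_double_prime} (Pa), \code{eta} (Pa s),
#'   \code{omega}, \code{gamma_0} and the number of whole cycles used.
#' @export
extract_moduli <- function(sigma_t, gamma_t, omega, time = NULL, dt = NULL) {
  stopifnot(length(sigma_t) == length(gamma_t), omega > 0)
  if (is.null(time)) {
    if (is.null(dt)) stop("supply either 'time' or 'dt'")
    time <- (seq_along(sigma_t) - 1) * dt
  }
  n <- length(time)
  if (n < 8) stop("record too short")
  step <- diff(time[1:2])
  span <- time[n] - time[1] + step  # closed period grid
  period <- 2 * pi / omega
  n_cycles <- span / period
  if (abs(n_cycles - round(n_cycles)) > 0.01)
    stop(sprintf(
      "record must cover a whole number of cycles (got %.3f cycles)",
      n_cycles))
  n_cycles <- round(n_cycles)
  if (n_cycles < 2) stop("need at least 2 full cycles")
  s <- sin(omega * time); co <- cos(omega * time)
  gamma_0 <- 2 * mean(gamma_t * s)
  if (abs(gamma_0) < .Machine$double.eps * 100)
    stop("strain amplitude is zero")
  Gp <- 2 * mean(sigma_t * s) / gamma_0
  Gpp <- 2 * mean(sigma_t * co) / gamma_0
  structure(list(G_prime = Gp, G_double_prime = Gpp,
                 eta = Gpp / omega, omega = omega, gamma_0 = gamma_0,
                 n_cycles = n_cycles),
            class = "viscoelastic_moduli")
}

#' @export
print.viscoelastic_moduli <- function(x, ...) {
  cat(sprintf(
    "Viscoelastic moduli (omega = %.4g rad/s, gamma_0 = %.4g, %d cycles)\n",
    x$omega, x$gamma_0, x$n_cycles))
  cat(sprintf("  G' = %.6g Pa, G'' = %.6g Pa, eta = %.6g Pa s\n",
              x$G_prime, x$G_double_prime, x$eta))
  invisible(x)
}

#' Shear viscosity from the loss modulus
#'
#' \eqn{\eta = G''/\omega}. (The source formalism states this in its
#' methods; a product form appearing once elsewhere is dimensionally
#' inconsistent for Pa s and is not used.)
#'
#' @param G_double_prime loss modulus (Pa).
#' @param omega angular frequency (rad/s, > 0).
#' @return Viscosity in Pa s.
#' @export
viscosity <- function(G_double_prime, omega) {
  if (!is.numeric(omega) || any(omega <= 0)) stop("'omega' must be > 0")
  G_double_prime / omega
}

#' Synthesise an oscillatory stress/strain record
#'
#' Builds the strain \eqn{\gamma_0 \sin(\omega t)} and the linear
#' viscoelastic stress for given moduli, optionally with additive Gaussian
#' stress noise — the construction inverse of \code{\link{extract_moduli}},
#' used for round-trip validation and synthetic rheology data.
#'
#' @param G_prime,G_double_prime target moduli (Pa).
#' @param gamma_0 strain amplitude.
#' @param omega angular frequency (rad/s).
#' @param n_cycles number of whole cycles (>= 2).
#' @param samples_per_cycle sampling density.
#' @param noise_sd sd of additive stress noise (Pa).
#' @return A data frame with columns \code{time}, \code{gamma},
#'   \code{sigma_xy}.
#' @export
synthesize_oscillation <- function(G_prime, G_double_prime, gamma_0,
                                   omega = 2 * pi, n_cycles = 4,
                                   samples_per_cycle = 256, noise_sd = 0) {
  stopifnot(n_cycles >= 2, gamma_0 > 0, omega > 0)
  period <- 2 * pi / omega
  dt <- period / samples_per_cycle
  time <- seq(0, n_cycles * period - dt, by = dt)
  gamma <- gamma_0 * sin(omega * time)
  sigma <- gamma_0 * (G_prime * sin(omega * time) +
                      G_double_prime * cos(omega * time))
  if (noise_sd > 0) sigma <- sigma + stats::rnorm(length(time), 0, noise_sd)
  data.frame(time = time, gamma = gamma, sigma_xy = sigma)
}

#' Detect the yield strain of an amplitude-sweep stress curve
#'
#' Fits the Hookean regime (stress proportional to strain) to the
#' lowest-amplitude points and reports the smallest amplitude whose stress
#' deviates from that linear prediction by more than \code{threshold}
#' (relative). If no amplitude deviates the curve is linear throughout and
#' \code{detected} is \code{FALSE}.
#'
#' @param curve a \code{\link{stress_strain_curve}} (>= 5 amplitudes for a
#'   meaningful detection).
#' @param threshold relative deviation defining yield, in (0, 1); default
#'   0.10 (the source identifies the yield point visually; 10% is this
#'   package's explicit criterion).
#' @param n_linear number of low-amplitude points used for the linear fit
#'   (>= 3).
#' @return An object of class \code{"yield_analysis"}: list with
#'   \code{gamma_Y} (NA when not detected), \code{linear_slope} (the
#'   Hookean modulus, Pa) and \code{detected}.
#' @export
detect_yield <- function(curve, threshold = 0.1, n_linear = 3) {
  stopifnot(inherits(curve, "data.frame"),
            all(c("gamma0", "stress") %in% names(curve)))
  if (!(threshold > 0 && threshold < 1)) stop("'threshold' must be in (0,1)")
  if (n_linear < 3) stop("need >= 3 points in the candidate linear regime")
  if (nrow(curve) < n_linear)
    stop("need >= ", n_linear, " amplitudes, got ", nrow(curve))
  g <- curve$gamma0; s <- curve$stress
  # proportional fit through the origin on the lowest amplitudes
  sel <- seq_len(n_linear)
  slope <- sum(s[sel] * g[sel]) / sum(g[sel]^2)
  dev <- abs(s - slope * g) / (slope * g)
  idx <- which(dev > threshold & seq_along(g) > n_linear)
  structure(list(gamma_Y = if (length(idx)) g[min(idx)] else NA_real_,
                 linear_slope = slope,
                 detected = length(idx) > 0,
                 threshold = threshold),
            class = "yield_analysis")
}

#' @export
print.yield_analysis <- function(x, ...) {
  if (x$detected)
    cat(sprintf("Yield detected at gamma_Y = %.4g (linear modulus %.4g Pa, threshold %.0f%%)\n",
                x$gamma_Y, x$linear_slope, 100 * x$threshold))
  else
    cat(sprintf("No yield detected (linear modulus %.4g Pa)\n",
                x$linear_slope))
  invisible(x)
}
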