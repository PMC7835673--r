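#' Specification for the synthetic-observation generators
#'
#' Bundles everything the generators need to emulate the study's
#' observables: the generating ("true") population parameters, the
#' observation grid and replicate count of the experimental design
#' (24/48/72/96 h, n = 10), the count noise (additive Gaussian on log10,
#' i.e. lognormal on the linear scale, default sd 0.1 log10 units — a
#' declared stand-in matched by eye to plate-count error bars), the
#' surface-coverage curve shape, and the per-condition rheology targets
#' (storage/loss modulus in Pa and yield strain).
#'
#' @param condition \code{"shaking"} or \code{"static"}.
#' @param true_params generating \code{\link{population_params}}; default
#'   \code{preset_params(condition)}.
#' @param times observation grid (h).
#' @param n_replicates replicates per time point (>= 1).
#' @param noise_sd_log10 sd of the log10 count noise (>= 0).
#' @param count_scale linear cells-per-density-unit factor mapping model
#'   densities to CFU-like magnitudes.
#' @param coverage_cap plateau of the zero-noise coverage curve (percent;
#'   default 55 under shaking, 35 static).
#' @param coverage_mid,coverage_width logistic-rise midpoint and width (h).
#' @param coverage_fall_start,coverage_fall_rate start (h) and relative
#'   rate (1/h) of the late decline (submerged-area detachment).
#' @param coverage_noise_sd sd of the truncated-Gaussian coverage noise
#'   (percentage points).
#' @param rheo_targets list with \code{G_prime}, \code{G_double_prime}
#'   (Pa) and \code{gamma_Y}; defaults are the published magnitudes
#'   (shaking: ~1 kPa, ~100 Pa, 0.2; static: ~10 Pa, ~10 Pa, 1.0).
#' @param stress_noise_sd sd of the multiplicative lognormal stress noise.
#' @param initial initial \code{\link{system_state}} for the count
#'   trajectory.
#' @param seed integer RNG seed; every generator output is a pure
#'   function of (spec, seed).
#' @return An object of class \code{"generator_spec"}.
#' @export
generator_spec <- function(condition = c("shaking", "static"),
                           true_params = NULL,
                           times = c(24, 48, 72, 96),
                           n_replicates = 10,
                           noise_sd_log10 = 0.1,
                           count_scale = 1e8,
                           coverage_cap = NULL,
                           coverage_mid = 24, coverage_width = 8,
                           coverage_fall_start = 60,
                           coverage_fall_rate = 0.005,
                           coverage_noise_sd = 5,
                           rheo_targets = NULL,
                           stress_noise_sd = 0.02,
                           initial = system_state(),
                           seed = 1) {
  condition <- match.arg(condition)
  if (is.null(true_params)) true_params <- preset_params(condition)
  if (is.null(coverage_cap))
    coverage_cap <- if (condition == "shaking") 55 else 35
  if (is.null(rheo_targets))
    rheo_targets <- if (condition == "shaking")
      list(G_prime = 1000, G_double_prime = 100, gamma_Y = 0.2)
    else
      list(G_prime = 10, G_double_prime = 10, gamma_Y = 1.0)
  stopifnot(noise_sd_log10 >= 0, n_replicates >= 1, all(times >= 0),
            coverage_cap > 0, coverage_cap <= 100,
            inherits(true_params, "population_params"))
  structure(list(condition = condition, true_params = true_params,
                 times = times, n_replicates = as.integer(n_replicates),
                 noise_sd_log10 = noise_sd_log10, count_scale = count_scale,
                 coverage_cap = coverage_cap, coverage_mid = coverage_mid,
                 coverage_width = coverage_width,
                 coverage_fall_start = coverage_fall_start,
                 coverage_fall_rate = coverage_fall_rate,
                 coverage_noise_sd = coverage_noise_sd,
                 rheo_targets = rheo_targets,
                 stress_noise_sd = stress_noise_sd,
                 initial = initial, seed = as.integer(seed)),
            class = "generator_spec")
}

with_spec_seed <- function(spec, offset, expr) {
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed((spec$seed + offset) %% .Machine$integer.max)
  force(expr)
}

#' Generate synthetic cell-count observations
#'
#' Integrates the population model with the spec's true parameters, samples
#' biofilm and planktonic densities at the observation grid, converts them
#' to log10 CFU-like values and adds i.i.d. Gaussian noise on the log10
#' scale per replicate (multiplicative plate-count error).
#'
#' @param spec a \code{\link{generator_spec}}.
#' @return A \code{\link{timeseries_table}} with variables
#'   \code{log10_cfu_biofilm} and \code{log10_cfu_plankton}.
#' @export
gen_counts <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  tr <- simulate_population(spec$true_params, initial = spec$initial,
                            t_end = max(spec$times), dt = 0.01)
  with_spec_seed(spec, 0L, {
    rows <- expand.grid(replicate = seq_len(spec$n_replicates),
                        time_h = spec$times,
                        variable = c("log10_cfu_biofilm", "log10_cfu_plankton"),
                        stringsAsFactors = FALSE)
    dens <- ifelse(rows$variable == "log10_cfu_biofilm",
                   stats::approx(tr$time_h, tr$rho_b, xout = rows$time_h)$y,
                   stats::approx(tr$time_h, tr$rho_p, xout = rows$time_h)$y)
    noise <- if (spec$noise_sd_log10 > 0)
      stats::rnorm(nrow(rows), 0, spec$noise_sd_log10) else 0
    timeseries_table(time_h = rows$time_h, condition = spec$condition,
                     replicate = rows$replicate, variable = rows$variable,
                     value = log10(dens * spec$count_scale) + noise)
  })
}

coverage_curve <- function(spec, t) {
  rise <- stats::plogis((t - spec$coverage_mid) / spec$coverage_width)
  fall <- pmax(0, 1 - spec$coverage_fall_rate *
                    pmax(0, t - spec$coverage_fall_start))
  pmin(spec$coverage_cap * rise * fall, 100)
}

#' Generate synthetic surface-coverage observations
#'
#' A saturating logistic rise to a condition-dependent cap with a mild late
#' decline (detachment of the submerged biofilm), plus truncated Gaussian
#' noise; all values clamped to [0, 100]. The zero-noise shaking curve
#' peaks inside the experimentally observed 48--72 h window.
#'
#' @param spec a \code{\link{generator_spec}}.
#' @return A \code{\link{timeseries_table}} with variable
#'   \code{coverage_pct}.
#' @export
gen_coverage <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  with_spec_seed(spec, 1L, {
    rows <- expand.grid(replicate = seq_len(spec$n_replicates),
                        time_h = spec$times)
    mu <- coverage_curve(spec, rows$time_h)
    val <- mu + if (spec$coverage_noise_sd > 0)
      stats::rnorm(nrow(rows), 0, spec$coverage_noise_sd) else 0
    timeseries_table(time_h = rows$time_h, condition = spec$condition,
                     replicate = rows$replicate, variable = "coverage_pct",
                     value = pmin(pmax(val, 0), 100))
  })
}

#' Generate a synthetic stress-strain curve
#'
#' Piecewise amplitude-sweep curve: Hookean regime with slope given by the
#' spec's storage-modulus target up to the yield strain, then a plastic
#' plateau with mild power-law softening; multiplicative lognormal noise.
#'
#' @param spec a \code{\link{generator_spec}} (its \code{condition} selects
#'   the yield strain: 0.2 for shaking, 1.0 for static, by default).
#' @param amplitudes strain-amplitude sweep (strictly increasing); default
#'   24 log-spaced points in [0.005, 4].
#' @param softening power-law softening exponent beyond yield (>= 0).
#' @return A \code{"stress_strain_curve"}: data frame with columns
#'   \code{gamma0} and \code{stress} (Pa), with the generating targets in
#'   attributes.
#' @export
gen_stress_strain <- function(spec, amplitudes = NULL, softening = 0.1) {
  stopifnot(inherits(spec, "generator_spec"))
  if (is.null(amplitudes))
    amplitudes <- exp(seq(log(0.005), log(4), length.out = 24))
  if (is.unsorted(amplitudes, strictly = TRUE))
    stop("amplitudes must be strictly increasing")
  G <- spec$rheo_targets$G_prime
  gY <- spec$rheo_targets$gamma_Y
  stress <- ifelse(amplitudes <= gY, G * amplitudes,
                   G * gY * (amplitudes / gY)^(-softening))
  with_spec_seed(spec, 2L, {
    if (spec$stress_noise_sd > 0)
      stress <- stress * exp(stats::rnorm(length(stress), 0,
                                          spec$stress_noise_sd))
    stress_strain_curve(amplitudes, stress, condition = spec$condition,
                        targets = spec$rheo_targets)
  })
}

#' Stress-strain curve container
#'
#' Per-amplitude records of an oscillatory amplitude sweep: strain
#' amplitude \code{gamma0} (strictly increasing) and the corresponding
#' stress response (first-harmonic or peak stress, Pa).
#'
#' @param gamma0 strain amplitudes (strictly increasing, > 0).
#' @param stress stress response per amplitude.
#' @param condition optional label.
#' @param targets optional generating targets kept as metadata.
#' @return An object of class \code{"stress_strain_curve"}.
#' @export
stress_strain_curve <- function(gamma0, stress, condition = NA_character_,
                                targets = NULL) {
  stopifnot(length(gamma0) == length(stress), all(gamma0 > 0))
  if (is.unsorted(gamma0, strictly = TRUE))
    stop("amplitudes must be strictly increasing")
  structure(data.frame(gamma0 = gamma0, stress = stress),
            condition = condition, targets = targets,
            class = c("stress_strain_curve", "data.frame"))
}

#' @export
print.stress_strain_curve <- function(x, ...) {
  cat(sprintf("Stress-strain curve%s: %d amplitudes in [%.3g, %.3g]\n",
              if (is.na(attr(x, "condition"))) ""
              else paste0(" [", attr(x, "condition"), "]"),
              nrow(x), min(x$gamma0), max(x$gamma0)))
  invisible(x)
}
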