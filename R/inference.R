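#' Normalise cell-count series to their 24 h value
#'
#' Count variables (\code{log10_cfu_biofilm}, \code{log10_cfu_plankton})
#' are divided, on the linear scale, by the value of the same
#' condition/replicate/variable series at the anchor time, so the anchor
#' observation maps to exactly 1 (0 on the log10 scale). Non-count
#' variables pass through untouched. The operation is idempotent.
#'
#' @param table a \code{\link{timeseries_table}}.
#' @param anchor_time anchor in hours (default 24).
#' @return The normalised table (count values are log10 of the normalised
#'   counts).
#' @export
normalize_to_24h <- function(table, anchor_time = 24) {
  validate_timeseries(table)
  counts <- table$variable %in% c("log10_cfu_biofilm", "log10_cfu_plankton")
  if (!any(counts)) return(table)
  key <- interaction(table$condition, table$replicate, table$variable,
                     drop = TRUE)
  for (k in levels(key)) {
    idx <- which(key == k & counts)
    if (!length(idx)) next
    at <- idx[abs(table$time_h[idx] - anchor_time) < 1e-8]
    if (length(at) == 0)
      stop("no ", anchor_time, " h anchor observation in series ", k,
           call. = FALSE)
    table$value[idx] <- table$value[idx] - table$value[at[1]]
  }
  table
}

#' Sum-of-squares loss of the population model against normalised counts
#'
#' Simulates the two-compartment model and accumulates squared residuals
#' between the model's log10 cell densities, normalised to their own 24 h
#' value, and the observed normalised log10 counts at the observation times
#' (model values linearly interpolated on the trajectory grid). A model
#' blow-up or a non-positive 24 h model density yields \code{+Inf}, never
#' an exception.
#'
#' @param params a \code{\link{population_params}} object.
#' @param table a normalised \code{\link{timeseries_table}}
#'   (see \code{\link{normalize_to_24h}}).
#' @param dt integration step (h).
#' @param initial initial \code{\link{system_state}}.
#' @param anchor_time normalisation anchor (h).
#' @return Scalar sum of squared log10 residuals (>= 0), or \code{Inf}.
#' @export
count_loss <- function(params, table, dt = 0.05, initial = system_state(),
                       anchor_time = 24) {
  counts <- table$variable %in% c("log10_cfu_biofilm", "log10_cfu_plankton")
  obs <- table[counts, ]
  if (nrow(obs) == 0) return(0)
  t_end <- max(obs$time_h, anchor_time)
  tr <- tryCatch(
    simulate_population(params, initial = initial, t_end = t_end, dt = dt),
    error = function(e) NULL, warning = function(w) suppressWarnings(
      simulate_population(params, initial = initial, t_end = t_end, dt = dt)))
  if (is.null(tr)) return(Inf)
  model_log10 <- function(var) {
    dens <- if (var == "log10_cfu_biofilm") tr$rho_b else tr$rho_p
    anchor <- stats::approx(tr$time_h, dens, xout = anchor_time)$y
    if (!is.finite(anchor) || anchor <= 0) return(NULL)
    function(t) log10(stats::approx(tr$time_h, dens, xout = t)$y / anchor)
  }
  ssr <- 0
  for (var in unique(obs$variable)) {
    f <- model_log10(var)
    if (is.null(f)) return(Inf)
    sel <- obs$variable == var
    pred <- f(obs$time_h[sel])
    if (any(!is.finite(pred))) return(Inf)
    ssr <- ssr + sum((pred - obs$value[sel])^2)
  }
  ssr
}

#' Fit exchange parameters of the population model to count data
#'
#' Bounded multi-start local least-squares in log10 parameter space:
#' \code{n_restarts} Latin-hypercube starting points inside the bounds,
#' each refined with \code{L-BFGS-B}, best restart returned. Deterministic
#' given \code{seed}; the caller's RNG state is restored on exit.
#'
#' @param table a \code{\link{timeseries_table}} of counts (normalised or
#'   not; it is normalised internally).
#' @param free names of the parameters to estimate (default the three
#'   transport rates that distinguish the growth conditions).
#' @param bounds two-column matrix (lower, upper) with one row per free
#'   parameter, or a single pair recycled to all; default
#'   \code{c(1e-4, 10)} 1/h, bracketing both presets with two decades of
#'   margin.
#' @param n_restarts number of Latin-hypercube restarts (>= 1).
#' @param start optional named vector of starting values for the free
#'   parameters; when given it replaces the first restart's Latin-hypercube
#'   point.
#' @param seed integer seed for the restart design.
#' @param base a \code{\link{population_params}} supplying the fixed
#'   (non-free) parameter values.
#' @param dt integration step used during fitting (h).
#' @param initial initial \code{\link{system_state}}.
#' @return An object of class \code{"biofilm_fit"}: estimated parameters
#'   (\code{$params}), the free estimates (\code{$estimates}, also via
#'   \code{coef}), best loss, bounds, convergence flag, restart count and
#'   seed.
#' @examples
#' \donttest{
#' spec <- generator_spec("shaking", n_replicates = 3, seed = 7)
#' fit <- fit_population(gen_counts(spec), n_restarts = 4, seed = 1)
#' coef(fit)
#' }
#' @export
fit_population <- function(table, free = c("k_plus", "k_minus", "D_n"),
                           bounds = c(1e-4, 10), n_restarts = 16, seed = 1,
                           start = NULL, base = population_params(),
                           dt = 0.05, initial = system_state()) {
  stopifnot(n_restarts >= 1, all(free %in% names(base)))
  if (is.null(dim(bounds)))
    bounds <- matrix(rep(as.numeric(bounds), length.out = 2 * length(free)),
                     ncol = 2, byrow = TRUE,
                     dimnames = list(free, c("lower", "upper")))
  if (any(!is.finite(bounds)) || any(bounds <= 0))
    stop("bounds must be finite and positive (rates)")
  table <- normalize_to_24h(table)

  lb <- log10(bounds[, 1]); ub <- log10(bounds[, 2])
  objective <- function(lpar) {
    p <- base
    p[free] <- 10^lpar
    count_loss(p, table, dt = dt, initial = initial)
  }

  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(seed)
  # Latin hypercube over log10-bounds: one stratum per restart per dimension
  d <- length(free)
  starts <- sapply(seq_len(d), function(j) {
    lb[j] + (ub[j] - lb[j]) * (sample(n_restarts) - runif(n_restarts)) / n_restarts
  })
  starts <- matrix(starts, nrow = n_restarts)
  if (!is.null(start)) {
    stopifnot(all(free %in% names(start)))
    starts[1, ] <- log10(as.numeric(start[free]))
  }

  best <- NULL
  n_conv <- 0L
  for (r in seq_len(n_restarts)) {
    res <- tryCatch(
      stats::optim(starts[r, ], objective, method = "L-BFGS-B",
                   lower = lb, upper = ub,
                   control = list(maxit = 200, factr = 1e9)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) next
    if (res$convergence == 0) n_conv <- n_conv + 1L
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    best <- list(par = (lb + ub) / 2, value = Inf, convergence = 1L)

  est <- stats::setNames(10^best$par, free)
  params <- base
  params[free] <- est
  structure(list(params = params, estimates = est, loss = best$value,
                 bounds = bounds, converged = n_conv > 0 && is.finite(best$value),
                 n_restarts = n_restarts, n_converged = n_conv, seed = seed,
                 free = free, dt = dt, initial = initial),
            class = "biofilm_fit")
}

#' @export
coef.biofilm_fit <- function(object, ...) object$estimates

#' @export
print.biofilm_fit <- function(x, ...) {
  cat(sprintf("Population-model fit (%d restarts, seed %d)\n",
              x$n_restarts, x$seed))
  cat(sprintf("  loss = %.6g; converged: %s (%d/%d restarts)\n", x$loss,
              x$converged, x$n_converged, x$n_restarts))
  for (nm in x$free)
    cat(sprintf("  %-8s = %.4g 1/h  (bounds %.4g..%.4g)\n", nm,
                x$estimates[[nm]], x$bounds[nm, 1], x$bounds[nm, 2]))
  invisible(x)
}

#' @export
summary.biofilm_fit <- function(object, ...) {
  print(object)
  cat("Fixed parameters:\n")
  fixed <- setdiff(names(object$params), c(object$free, "c_ref"))
  for (nm in fixed) cat(sprintf("  %-8s = %.4g\n", nm, object$params[[nm]]))
  invisible(object)
}

#' @export
predict.biofilm_fit <- function(object, times = NULL, ...) {
  t_end <- if (is.null(times)) 96 else max(times, 24)
  tr <- simulate_population(object$params, initial = object$initial,
                            t_end = t_end, dt = object$dt)
  if (is.null(times)) times <- tr$time_h
  norm24 <- function(dens)
    log10(stats::approx(tr$time_h, dens, xout = times)$y /
          stats::approx(tr$time_h, dens, xout = 24)$y)
  data.frame(time_h = times,
             log10_cfu_biofilm = norm24(tr$rho_b),
             log10_cfu_plankton = norm24(tr$rho_p))
}
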