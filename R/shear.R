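#' DPD parameters for the bacteria-polymer-solvent network
#'
#' Community-standard water-like baseline in reduced units: number density
#' 3, like-pair repulsion 25, cutoff 1, temperature 1, dissipative friction
#' 4.5 with the random-force amplitude tied by fluctuation-dissipation
#' (\eqn{\sigma_r^2 = 2 \gamma_d k_B T}).
#'
#' @param density bead number density (1/r_c^3).
#' @param a_same conservative repulsion between like beads.
#' @param a_cross repulsion between unlike bead types (default equal to
#'   \code{a_same}; the coarse model carries no chemistry-specific
#'   asymmetry).
#' @param gamma_d dissipative friction.
#' @param kT target temperature.
#' @param dt integration timestep.
#' @param k_bond,r0_bond harmonic intra-molecule bond stiffness and rest
#'   length (polymer chains and bacterial rods).
#' @param k_xlink,r0_xlink crosslink stiffness and rest length.
#' @param chain_len beads per polymer chain.
#' @param bact_beads beads per (rod-shaped) bacterium.
#' @param sigma_r random-force amplitude; \code{NULL} (default) ties it to
#'   \code{gamma_d} and \code{kT} by fluctuation-dissipation. Setting it
#'   manually breaks detailed balance (useful only as a thermostat
#'   negative control).
#' @return An object of class \code{"dpd_params"}.
#' @export
dpd_params <- function(density = 3, a_same = 25, a_cross = 25,
                       gamma_d = 4.5, kT = 1, dt = 0.02,
                       k_bond = 100, r0_bond = 0.7,
                       k_xlink = 100, r0_xlink = 0.7,
                       chain_len = 10, bact_beads = 5, sigma_r = NULL) {
  stopifnot(density > 0, gamma_d > 0, kT > 0, dt > 0, chain_len >= 2,
            bact_beads >= 2)
  if (is.null(sigma_r)) sigma_r <- sqrt(2 * gamma_d * kT)
  structure(list(density = density, a_same = a_same, a_cross = a_cross,
                 gamma_d = gamma_d, sigma_r = sigma_r,
                 kT = kT, dt = dt, k_bond = k_bond, r0_bond = r0_bond,
                 k_xlink = k_xlink, r0_xlink = r0_xlink,
                 chain_len = chain_len, bact_beads = bact_beads),
            class = "dpd_params")
}

#' Oscillatory shear protocol
#'
#' Sinusoidal simple shear \eqn{\gamma(t) = \gamma_0 \sin(\omega t)}
#' imposed through Lees-Edwards boundaries (the experiments drive at 1 Hz;
#' the simulation frequency is in reduced units).
#'
#' @param gamma_0 strain amplitude (>= 0).
#' @param omega angular frequency (reduced units).
#' @param n_cycles number of cycles (>= 2; the first is discarded as
#'   transient).
#' @return An object of class \code{"shear_protocol"}.
#' @export
shear_protocol <- function(gamma_0 = 0.2, omega = 0.2, n_cycles = 4) {
  stopifnot(gamma_0 >= 0, omega > 0, n_cycles >= 2)
  structure(list(gamma_0 = gamma_0, omega = omega,
                 n_cycles = as.integer(n_cycles)),
            class = "shear_protocol")
}

a_matrix <- function(params) {
  a <- matrix(params$a_cross, 3, 3)
  diag(a) <- params$a_same
  a
}

#' Build a bacteria-polymer-solvent DPD system
#'
#' Composes the non-solvent fraction according to the measured
#' biovolume ratios — bacteria:polymer 53:47 under shaking, 72:28 under
#' static growth — fills the rest with solvent, renders polymers as
#' bead-spring chains and bacteria as short stiff bead rods, and
#' equilibrates the unsheared system.
#'
#' @param condition \code{"shaking"} or \code{"static"}.
#' @param L box side (reduced units); bead count is
#'   \code{round(density L^3)} (keep below ~2e4).
#' @param params a \code{\link{dpd_params}}.
#' @param non_solvent_frac bead fraction occupied by bacteria + polymer.
#' @param equil_steps equilibration steps before return.
#' @param seed integer RNG seed; identical seed/size/condition give an
#'   identical configuration.
#' @return An object of class \code{"shear_system"}: bead positions,
#'   velocities, types (0 solvent, 1 polymer, 2 bacterium), molecular
#'   bonds, crosslink registry and composition metadata.
#' @export
build_shear_system <- function(condition = c("shaking", "static"), L = 5,
                               params = dpd_params(),
                               non_solvent_frac = 0.3,
                               equil_steps = 2000, seed = 1) {
  condition <- match.arg(condition)
  n <- round(params$density * L^3)
  if (n > 2e4) stop("requested size exceeds the desk-scale bound (~2e4 beads)")
  bact_frac <- if (condition == "shaking") 0.53 else 0.72
  n_target <- round(non_solvent_frac * n)
  n_bact_beads <- round(n_target * bact_frac)
  n_poly_beads <- n_target - n_bact_beads
  n_bact <- max(1, round(n_bact_beads / params$bact_beads))
  n_chain <- max(1, round(n_poly_beads / params$chain_len))
  n_struct <- n_bact * params$bact_beads + n_chain * params$chain_len
  if (n_struct >= n)
    stop("composition infeasible at this size: ", n_struct,
         " structured beads for ", n, " total")

  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(seed)

  place_molecule <- function(n_beads, spacing) {
    p <- matrix(0, n_beads, 3)
    p[1, ] <- stats::runif(3, 0, L)
    for (k in seq_len(n_beads - 1)) {
      dir <- stats::rnorm(3)
      p[k + 1, ] <- p[k, ] + spacing * dir / sqrt(sum(dir^2))
    }
    p
  }
  place_rod <- function(n_beads, spacing) {
    o <- stats::runif(3, 0, L)
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    t(vapply(seq_len(n_beads) - 1, function(k) o + k * spacing * dir,
             numeric(3)))
  }

  pos <- NULL; type <- integer(0); mol <- integer(0)
  bonds <- NULL
  add_bonds <- function(bonds, offset, nb, k, r0, stiff_rod) {
    # 1-based bead indices
    b <- cbind(offset + seq_len(nb - 1), offset + seq_len(nb - 1) + 1, k, r0)
    if (stiff_rod && nb > 2)  # next-nearest bonds keep rods straight
      b <- rbind(b, cbind(offset + seq_len(nb - 2),
                          offset + seq_len(nb - 2) + 2, k, 2 * r0))
    rbind(bonds, b)
  }
  mol_id <- 0L
  for (i in seq_len(n_bact)) {
    mol_id <- mol_id + 1L
    off <- if (is.null(pos)) 0L else nrow(pos)
    pos <- rbind(pos, place_rod(params$bact_beads, 0.5))
    type <- c(type, rep(2L, params$bact_beads))
    mol <- c(mol, rep(mol_id, params$bact_beads))
    bonds <- add_bonds(bonds, off, params$bact_beads, 2 * params$k_bond, 0.5,
                       TRUE)
  }
  for (i in seq_len(n_chain)) {
    mol_id <- mol_id + 1L
    off <- nrow(pos)
    pos <- rbind(pos, place_molecule(params$chain_len, params$r0_bond))
    type <- c(type, rep(1L, params$chain_len))
    mol <- c(mol, rep(mol_id, params$chain_len))
    bonds <- add_bonds(bonds, off, params$chain_len, params$k_bond,
                       params$r0_bond, FALSE)
  }
  n_solv <- n - nrow(pos)
  pos <- rbind(pos, matrix(stats::runif(3 * n_solv, 0, L), ncol = 3))
  type <- c(type, rep(0L, n_solv))
  mol <- c(mol, rep(0L, n_solv))
  vel <- matrix(stats::rnorm(3 * n, 0, sqrt(params$kT)), ncol = 3)
  vel <- sweep(vel, 2, colMeans(vel))  # zero total momentum

  sys <- structure(list(pos = pos, vel = vel, type = type, mol = mol,
                        bonds = bonds[, 1:2, drop = FALSE],
                        bond_k = bonds[, 3], bond_r0 = bonds[, 4],
                        n_molecular_bonds = nrow(bonds),
                        crosslinks = matrix(integer(0), 0, 2),
                        L = L, params = params, condition = condition,
                        composition = c(bacteria = n_bact_beads / n_target,
                                        polymer = n_poly_beads / n_target),
                        seed = seed),
                   class = "shear_system")
  if (equil_steps > 0) sys <- run_dpd(sys, equil_steps, record_every = 0)
  sys
}

#' @export
print.shear_system <- function(x, ...) {
  cat(sprintf("DPD shear system [%s]: %d beads (L = %g), %d bonds, %d crosslinks\n",
              x$condition, nrow(x$pos), x$L, nrow(x$bonds),
              nrow(x$crosslinks)))
  cat(sprintf("  non-solvent composition: %.0f%% bacteria / %.0f%% polymer\n",
              100 * x$composition[["bacteria"]],
              100 * x$composition[["polymer"]]))
  invisible(x)
}

# low-level driver; gamma0 = 0 means unsheared (equilibration) dynamics
run_dpd <- function(sys, n_steps, protocol = NULL, record_every = 1) {
  p <- sys$params
  gamma0 <- if (is.null(protocol)) 0 else protocol$gamma_0
  omega <- if (is.null(protocol)) 1 else protocol$omega
  all_bonds <- rbind(sys$bonds, sys$crosslinks)
  bond_k <- c(sys$bond_k, rep(p$k_xlink, nrow(sys$crosslinks)))
  bond_r0 <- c(sys$bond_r0, rep(p$r0_xlink, nrow(sys$crosslinks)))
  res <- dpd_run_cpp(sys$pos, sys$vel, sys$type,
                     matrix(as.integer(all_bonds), ncol = 2) - 1L,
                     bond_k, bond_r0, sys$L, a_matrix(p), p$gamma_d,
                     p$sigma_r, p$kT, p$dt, as.integer(n_steps), gamma0,
                     omega, as.integer(record_every))
  sys$pos <- res$pos
  sys$vel <- res$vel
  sys$last_record <- res$record
  sys
}

#' Gradually add crosslinks to a shear system
#'
#' Creates \code{n_links} harmonic links between distinct non-solvent
#' beads of different molecules within the capture radius, in batches with
#' unsheared relaxation in between (gradual network formation). Fails,
#' reporting the placed count, if eligible pairs run out.
#'
#' @param sys a \code{"shear_system"}.
#' @param n_links number of links to add (>= 0).
#' @param capture_radius maximum bead separation for a new link
#'   (default 1.2 r_c).
#' @param batches number of placement batches with relaxation in between.
#' @param relax_steps unsheared steps after each batch.
#' @param seed integer RNG seed.
#' @return The system with \code{nrow(crosslinks)} grown by exactly
#'   \code{n_links}.
#' @export
add_crosslinks <- function(sys, n_links, capture_radius = 1.2, batches = 5,
                           relax_steps = 200, seed = 1) {
  stopifnot(inherits(sys, "shear_system"), n_links >= 0)
  if (n_links == 0) return(sys)
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(seed)
  remaining <- n_links
  batch_sizes <- diff(round(seq(0, n_links, length.out = batches + 1)))
  for (b in batch_sizes) {
    if (b == 0) next
    cand <- eligible_pairs(sys, capture_radius)
    if (nrow(cand) < b)
      stop("cannot place requested links within the capture radius: placed ",
           n_links - remaining, " of ", n_links)
    pick <- cand[sample(nrow(cand), b), , drop = FALSE]
    sys$crosslinks <- rbind(sys$crosslinks, pick)
    remaining <- remaining - b
    if (relax_steps > 0) sys <- run_dpd(sys, relax_steps, record_every = 0)
  }
  sys
}

# candidate polymer-polymer / polymer-bacterium pairs within the capture
# radius, excluding same-molecule pairs and already-linked pairs
eligible_pairs <- function(sys, capture_radius) {
  ns <- which(sys$type != 0L)
  p <- sys$pos[ns, , drop = FALSE] %% sys$L
  # minimum-image distance per axis
  for (ax in 1:3) {
    da <- outer(p[, ax], p[, ax], "-")
    da <- abs(da - sys$L * round(da / sys$L))
    if (ax == 1) d2 <- da^2 else d2 <- d2 + da^2
  }
  within <- which(upper.tri(d2) & d2 < capture_radius^2, arr.ind = TRUE)
  if (nrow(within) == 0) return(matrix(integer(0), 0, 2))
  i <- ns[within[, 1]]; j <- ns[within[, 2]]
  keep <- sys$mol[i] != sys$mol[j]
  i <- i[keep]; j <- j[keep]
  if (length(i) == 0) return(matrix(integer(0), 0, 2))
  existing <- paste(pmin(sys$crosslinks[, 1], sys$crosslinks[, 2]),
                    pmax(sys$crosslinks[, 1], sys$crosslinks[, 2]))
  keynew <- paste(pmin(i, j), pmax(i, j))
  keep <- !(keynew %in% existing) & !duplicated(keynew)
  cbind(i, j)[keep, , drop = FALSE]
}

#' Drive a system through oscillatory shear and record the stress
#'
#' Boundary-driven sinusoidal simple shear; the off-diagonal virial
#' stress (kinetic part with flow-subtracted peculiar velocities) is
#' recorded each step and the first cycle is discarded as transient.
#'
#' @param sys an equilibrated \code{"shear_system"}.
#' @param protocol a \code{\link{shear_protocol}}.
#' @param seed integer RNG seed.
#' @return A data frame \code{time, gamma, sigma_xy, temperature} of class
#'   \code{"shear_record"} with the protocol in attributes; kinetic
#'   temperature drifting more than 20\% off target raises an error.
#' @export
oscillate <- function(sys, protocol, seed = 1) {
  stopifnot(inherits(sys, "shear_system"), inherits(protocol, "shear_protocol"))
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(seed)
  period <- 2 * pi / protocol$omega
  steps_per_cycle <- round(period / sys$params$dt)
  n_steps <- steps_per_cycle * protocol$n_cycles
  sys <- run_dpd(sys, n_steps, protocol = protocol, record_every = 1)
  rec <- sys$last_record
  temp <- mean(rec$temperature)
  if (abs(temp - sys$params$kT) > 0.2 * sys$params$kT)
    stop(sprintf("thermostat failure: kinetic temperature %.3f vs target %.3f",
                 temp, sys$params$kT))
  rec <- rec[rec$time > period, ]  # drop the transient first cycle
  structure(rec, protocol = protocol, class = c("shear_record", "data.frame"))
}

#' First-harmonic stress response of a shear record
#'
#' The amplitude of the fundamental Fourier component of
#' \eqn{\sigma_{xy}(t)}, i.e. \eqn{|G^*| \gamma_0} — the lock-in measure
#' of the stress response used for the crosslink master curve.
#'
#' @param record a \code{"shear_record"} from \code{\link{oscillate}}.
#' @return List with \code{amplitude}, \code{G_prime}, \code{G_double_prime}
#'   (reduced units).
#' @export
stress_response <- function(record) {
  protocol <- attr(record, "protocol")
  m <- extract_moduli(record$sigma_xy, record$gamma, protocol$omega,
                      time = record$time)
  list(amplitude = sqrt(m$G_prime^2 + m$G_double_prime^2) * m$gamma_0,
       G_prime = m$G_prime, G_double_prime = m$G_double_prime)
}

#' Shaking/static stress-response ratio versus crosslink ratio
#'
#' For each crosslink ratio x the shaking-composition system receives
#' x times the static system's crosslink count; both are driven through
#' the same oscillatory protocol at each amplitude and the ratio of their
#' first-harmonic stress responses is averaged over amplitudes. Collapse
#' quality is reported as the spread across amplitudes. Individual run
#' failures flag the affected row rather than aborting the sweep.
#'
#' @param static_sys,shaking_sys equilibrated \code{"shear_system"}s.
#' @param crosslink_ratios numeric ratios (>= 1).
#' @param n_static_links crosslink count of the static reference.
#' @param amplitudes strain amplitudes (within the linear regime).
#' @param omega,n_cycles protocol settings shared by all runs.
#' @param seed integer RNG seed.
#' @return Data frame with columns \code{x_ratio}, \code{stress_ratio},
#'   \code{spread} (sd across amplitudes) and \code{failed}.
#' @export
stress_ratio_curve <- function(static_sys, shaking_sys, crosslink_ratios,
                               n_static_links = 50,
                               amplitudes = c(0.1, 0.2),
                               omega = 0.2, n_cycles = 4, seed = 1) {
  stopifnot(all(crosslink_ratios >= 1))
  st <- add_crosslinks(static_sys, n_static_links, seed = seed)
  st_resp <- vapply(amplitudes, function(g0) {
    rec <- oscillate(st, shear_protocol(g0, omega, n_cycles), seed = seed)
    stress_response(rec)$amplitude
  }, numeric(1))
  out <- lapply(crosslink_ratios, function(x) {
    tryCatch({
      sh <- add_crosslinks(shaking_sys, round(x * n_static_links),
                           seed = seed)
      r <- vapply(seq_along(amplitudes), function(k) {
        rec <- oscillate(sh, shear_protocol(amplitudes[k], omega, n_cycles),
                         seed = seed)
        stress_response(rec)$amplitude / st_resp[k]
      }, numeric(1))
      data.frame(x_ratio = x, stress_ratio = mean(r),
                 spread = if (length(r) > 1) stats::sd(r) else 0,
                 failed = FALSE)
    }, error = function(e)
      data.frame(x_ratio = x, stress_ratio = NA_real_, spread = NA_real_,
                 failed = TRUE))
  })
  do.call(rbind, out)
}

#' Published master-curve polynomial for the stress-response ratio
#'
#' Reference quadratic relating the shaking/static stress-response ratio
#' to the crosslink-number ratio x, with the published fitted
#' coefficients (0.75, 4.4, -1.14). At x = 6 it recovers the measured
#' storage-modulus ratio of ~50 (24 h biofilms) and at x = 12 ~150 (48 h).
#'
#' @param x crosslink-number ratio (>= 0); vectorised.
#' @return Predicted stress-response ratio \code{0.75 x^2 + 4.4 x - 1.14}.
#' @examples
#' evaluate_master_curve(c(6, 12))
#' @export
evaluate_master_curve <- function(x) {
  if (any(x < 0)) stop("'x' must be >= 0")
  master_curve_coef[["a2"]] * x^2 + master_curve_coef[["a1"]] * x +
    master_curve_coef[["a0"]]
}

#' @rdname evaluate_master_curve
#' @format NULL
#' @export
master_curve_coef <- c(a2 = 0.75, a1 = 4.4, a0 = -1.14)
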