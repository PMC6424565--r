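# A minimal stand-in for the MD force field and integrator: harmonic bonds
# and angles plus a soft-core repulsion, a steepest-descent minimizer, and
# Langevin (BAOAB) dynamics with a time-dependent target temperature.
# The force-provider contract -- a function (coords, time) returning
# list(energy, forces, ...) in kJ/mol and kJ/mol/nm -- is the only coupling
# surface between the engine and any potential; the fitting potential and
# the toy force field are interchangeable plug-ins.

KB_KJ_MOL_K <- 0.0083144621  # Boltzmann constant, kJ mol^-1 K^-1

#' Toy bonded topology
#'
#' @param bonds data frame with columns `i`, `j` (1-based atom indices),
#'   `b0` (equilibrium length, nm) and `kb` (kJ mol^-1 nm^-2).
#' @param angles data frame with columns `i`, `j`, `k` (vertex at `j`),
#'   `theta0` (rad) and `ktheta` (kJ mol^-1 rad^-2); may be empty.
#' @param repulsion list with `cutoff` (pair list cutoff, nm), `eps`
#'   (kJ mol^-1) and `r_min` (nm): pairs closer than `r_min` feel
#'   `eps * (1 - r/r_min)^2`; bonded pairs are excluded.
#' @param n_atoms number of atoms the topology refers to.
#' @return An object of class `toy_topology`.
#' @export
toy_topology <- function(bonds, angles = NULL, repulsion = NULL,
                         n_atoms = max(bonds$i, bonds$j)) {
  bonds <- as.data.frame(bonds)
  stopifnot(all(c("i", "j", "b0", "kb") %in% names(bonds)))
  if (any(bonds$i == bonds$j)) stop("self-bonds are not allowed")
  if (any(bonds$b0 <= 0)) stop("b0 must be > 0")
  idx <- c(bonds$i, bonds$j)
  if (!is.null(angles) && nrow(as.data.frame(angles)) > 0) {
    angles <- as.data.frame(angles)
    stopifnot(all(c("i", "j", "k", "theta0", "ktheta") %in% names(angles)))
    idx <- c(idx, angles$i, angles$j, angles$k)
  } else angles <- NULL
  if (any(idx < 1) || any(idx > n_atoms)) stop("topology index out of range")
  if (!is.null(repulsion)) {
    stopifnot(all(c("cutoff", "eps", "r_min") %in% names(repulsion)))
    if (repulsion$cutoff <= 0 || repulsion$r_min <= 0)
      stop("repulsion cutoff and r_min must be > 0")
  }
  nb_pairs <- NULL
  if (!is.null(repulsion)) {
    # non-bonded pair list, bonded pairs excluded (precomputed once)
    n <- as.integer(n_atoms)
    excl <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    pr <- which(upper.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
    key <- paste(pr[, 1], pr[, 2])
    nb_pairs <- pr[!(key %in% excl), , drop = FALSE]
  }
  structure(list(bonds = bonds, angles = angles, repulsion = repulsion,
                 nb_pairs = nb_pairs, n_atoms = as.integer(n_atoms)),
            class = "toy_topology")
}

#' Toy force-field energy and forces
#'
#' Sum of harmonic bond (`0.5 kb (r - b0)^2`), harmonic angle
#' (`0.5 ktheta (theta - theta0)^2`) and soft-core repulsion terms; forces
#' are exact analytic gradients.
#'
#' @param model an [atomic_model] (or n x 3 coordinate matrix, nm).
#' @param topo a [toy_topology].
#' @return List with `energy` (kJ mol^-1) and `forces` (n x 3,
#'   kJ mol^-1 nm^-1).
#' @export
toy_energy_forces <- function(model, topo) {
  x <- if (inherits(model, "atomic_model")) model$coords else as.matrix(model)
  if (topo$n_atoms > nrow(x)) stop("topology index out of range")
  n <- nrow(x)
  energy <- 0
  forces <- matrix(0, n, 3)
  b <- topo$bonds
  if (nrow(b) > 0) {
    dv <- x[b$j, , drop = FALSE] - x[b$i, , drop = FALSE]
    r <- sqrt(rowSums(dv^2))
    dr <- r - b$b0
    energy <- energy + sum(0.5 * b$kb * dr^2)
    fmag <- -b$kb * dr / r           # force on j along +dv
    fj <- dv * fmag
    for (c3 in 1:3) {
      forces[, c3] <- forces[, c3] +
        tabulate_add(n, b$j, fj[, c3]) - tabulate_add(n, b$i, fj[, c3])
    }
  }
  a <- topo$angles
  if (!is.null(a) && nrow(a) > 0) {
    rij <- x[a$i, , drop = FALSE] - x[a$j, , drop = FALSE]
    rkj <- x[a$k, , drop = FALSE] - x[a$j, , drop = FALSE]
    nij <- sqrt(rowSums(rij^2)); nkj <- sqrt(rowSums(rkj^2))
    cth <- rowSums(rij * rkj) / (nij * nkj)
    cth <- pmin(pmax(cth, -1 + 1e-12), 1 - 1e-12)
    th <- acos(cth)
    dth <- th - a$theta0
    energy <- energy + sum(0.5 * a$ktheta * dth^2)
    # dV/dtheta, distributed via the standard angle gradient
    coef <- a$ktheta * dth / sqrt(1 - cth^2)   # = -dV/dcos(theta)
    gi <- (rkj / nkj - rij * cth / nij) / nij  # d cos / d r_i
    gk <- (rij / nij - rkj * cth / nkj) / nkj
    fi <- coef * gi                            # force on i = -dV/dr_i
    fk <- coef * gk
    for (c3 in 1:3) {
      forces[, c3] <- forces[, c3] +
        tabulate_add(n, a$i, fi[, c3]) +
        tabulate_add(n, a$k, fk[, c3]) -
        tabulate_add(n, a$j, fi[, c3] + fk[, c3])
    }
  }
  rep_ <- topo$repulsion
  if (!is.null(rep_) && rep_$eps > 0) {
    pr <- topo$nb_pairs
    if (nrow(pr) > 0) {
      dv <- x[pr[, 2], , drop = FALSE] - x[pr[, 1], , drop = FALSE]
      r <- sqrt(rowSums(dv^2))
      close <- which(r < rep_$r_min & r > 0)
      if (length(close) > 0) {
        rr <- r[close]
        u <- 1 - rr / rep_$r_min
        energy <- energy + sum(rep_$eps * u^2)
        fmag <- 2 * rep_$eps * u / rep_$r_min / rr  # repulsive, on atom 2
        fj <- dv[close, , drop = FALSE] * fmag
        jx <- pr[close, 2]; ix <- pr[close, 1]
        for (c3 in 1:3) {
          forces[, c3] <- forces[, c3] +
            tabulate_add(n, jx, fj[, c3]) - tabulate_add(n, ix, fj[, c3])
        }
      }
    }
  }
  list(energy = energy, forces = forces)
}

tabulate_add <- function(n, idx, vals) {
  out <- numeric(n)
  agg <- rowsum(vals, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Force provider for the toy force field
#' @param topo a [toy_topology].
#' @return A provider function `(coords, time) -> list(energy, forces)` with
#'   attribute `role = "ff"`.
#' @export
toy_provider <- function(topo) {
  f <- function(coords, time = 0) toy_energy_forces(coords, topo)
  attr(f, "role") <- "ff"
  f
}

instability_condition <- function(msg, step, time) {
  structure(class = c("cdfit_instability", "error", "condition"),
            list(message = msg, call = NULL, step = step, time = time))
}

eval_providers <- function(providers, coords, time) {
  energy <- 0; vfit <- 0; vff <- 0; cc <- NA_real_
  forces <- matrix(0, nrow(coords), 3)
  for (p in providers) {
    r <- p(coords, time)
    energy <- energy + r$energy
    forces <- forces + r$forces
    if (identical(attr(p, "role"), "fit")) {
      vfit <- vfit + r$energy
      if (!is.null(r$cc)) cc <- r$cc
    } else vff <- vff + r$energy
  }
  list(energy = energy, forces = forces, vfit = vfit, vff = vff, cc = cc)
}

#' Steepest-descent energy minimization
#'
#' Adaptive-step steepest descent: a step is accepted if the total energy
#' decreases (step size then grows by 1.2), otherwise rejected and the step
#' size halved. Stops when `max |force| < tol` or after `max_steps`.
#'
#' @param model an [atomic_model].
#' @param potentials list of force providers.
#' @param max_steps maximum iterations (default 1000).
#' @param tol force tolerance, kJ mol^-1 nm^-1 (default 1).
#' @param step0 initial displacement of the largest force component, nm.
#' @return The minimized [atomic_model] with attributes `energy`, `steps`
#'   (accepted steps) and `max_force`.
#' @export
minimize <- function(model, potentials, max_steps = 1000, tol = 1,
                     step0 = 0.01) {
  if (length(potentials) < 1) stop("need at least one force provider")
  x <- model$coords
  ev <- eval_providers(potentials, x, 0)
  if (!is.finite(ev$energy)) stop("NaN energy at start of minimization")
  step <- step0
  accepted <- 0L
  for (it in seq_len(max_steps)) {
    fmax <- max(abs(ev$forces))
    if (fmax < tol) break
    trial <- x + ev$forces * (step / fmax)
    evt <- eval_providers(potentials, trial, 0)
    if (!is.finite(evt$energy))
      stop("NaN energy during minimization at step ", it)
    if (evt$energy < ev$energy) {
      x <- trial; ev <- evt
      accepted <- accepted + 1L
      step <- step * 1.2
    } else {
      step <- step * 0.5
      if (step < 1e-12) break
    }
  }
  out <- set_coords(model, x)
  attr(out, "energy") <- ev$energy
  attr(out, "steps") <- accepted
  attr(out, "max_force") <- max(abs(ev$forces))
  out
}

#' Thermostat schedule
#'
#' Piecewise-linear target temperature versus time; evaluation clamps
#' outside the first/last node.
#'
#' @param times ascending times (ps).
#' @param temps target temperatures (K, >= 0), one per time.
#' @param friction Langevin friction (ps^-1, > 0).
#' @param seed integer seed for the thermal noise.
#' @return An object of class `thermostat_schedule`.
#' @export
thermostat_schedule <- function(times, temps, friction = 5, seed = 1) {
  times <- as.numeric(times); temps <- as.numeric(temps)
  if (length(times) != length(temps)) stop("times and temps lengths differ")
  if (is.unsorted(times)) stop("times must be ascending")
  if (any(temps < 0)) stop("temps must be >= 0")
  if (friction <= 0) stop("friction must be > 0")
  structure(list(times = times, temps = temps, friction = friction,
                 seed = as.integer(seed)),
            class = "thermostat_schedule")
}

temp_at <- function(th, t) {
  if (length(th$times) == 1) return(th$temps)
  approx(th$times, th$temps, xout = t, rule = 2)$y
}

#' Langevin dynamics with a time-dependent target temperature
#'
#' BAOAB splitting. Identical seeds give bitwise-identical trajectories;
#' at `T = 0` with zero forces the coordinates stay constant. Snapshots
#' record time, coordinates, `cc`, `Vfit`, `Vff` and the target temperature,
#' all recomputed fresh from the snapshot coordinates.
#'
#' @param model an [atomic_model]; initial velocities are zero.
#' @param potentials list of force providers.
#' @param thermostat a [thermostat_schedule].
#' @param dt time step (ps). A warning is issued when `dt` exceeds a tenth
#'   of the stiffest bond period estimate.
#' @param n_steps number of integration steps.
#' @param stride steps between snapshots (default: 100).
#' @param t0 time of the first step's start (default 0); schedules are
#'   evaluated at absolute time `t0 + step * dt`.
#' @param topo optional [toy_topology] for the stability estimate.
#' @return An object of class `trajectory`: list with `times`, `coords`
#'   (n x 3 x n_snap array), `cc`, `vfit`, `vff`, `t_target`, `stride`, `dt`.
#' @export
integrate_langevin <- function(model, potentials, thermostat, dt, n_steps,
                               stride = 100L, t0 = 0, topo = NULL) {
  if (length(potentials) < 1) stop("need at least one force provider")
  if (!is.null(topo) && nrow(topo$bonds) > 0) {
    omega_max <- sqrt(max(topo$bonds$kb) / min(model$masses))
    if (dt > 0.1 * 2 * pi / omega_max)
      warning(sprintf("dt = %g ps may be unstable for the stiffest bond (limit ~%.2g ps)",
                      dt, 0.1 * 2 * pi / omega_max))
  }
  set.seed(thermostat$seed)
  n <- n_atoms(model)
  x <- model$coords
  v <- matrix(0, n, 3)
  m <- model$masses
  gamma <- thermostat$friction
  c1 <- exp(-gamma * dt)
  c2 <- sqrt(1 - c1^2)
  snaps <- seq(stride, n_steps, by = stride)
  n_snap <- length(snaps)
  out_coords <- array(NA_real_, dim = c(n, 3, n_snap))
  out <- list(times = numeric(n_snap), cc = numeric(n_snap),
              vfit = numeric(n_snap), vff = numeric(n_snap),
              t_target = numeric(n_snap))
  ev <- eval_providers(potentials, x, t0)
  isnap <- 0L
  for (step in seq_len(n_steps)) {
    t_mid <- t0 + (step - 0.5) * dt
    t_end <- t0 + step * dt
    v <- v + (dt / 2) * ev$forces / m
    x <- x + (dt / 2) * v
    kT <- KB_KJ_MOL_K * temp_at(thermostat, t_mid)
    if (kT > 0) {
      v <- c1 * v + c2 * sqrt(kT / m) * matrix(rnorm(3 * n), n, 3)
    } else {
      v <- c1 * v
    }
    x <- x + (dt / 2) * v
    ev <- tryCatch(
      eval_providers(potentials, x, t_end),
      error = function(e) {
        if (inherits(e, "cdfit_instability")) stop(e)
        # a provider failing mid-trajectory (e.g. atoms leaving the grid)
        # is a numerical abort, not a validation error
        stop(instability_condition(sprintf(
          "numerical instability at step %d (t = %g ps): %s",
          step, t_end, conditionMessage(e)), step, t_end))
      })
    v <- v + (dt / 2) * ev$forces / m
    if (!all(is.finite(x)) || !is.finite(ev$energy))
      stop(instability_condition(sprintf(
        "numerical instability at step %d (t = %g ps): max |force| = %g",
        step, t_end, suppressWarnings(max(abs(ev$forces), na.rm = TRUE))),
        step, t_end))
    if (step %in% snaps) {
      isnap <- isnap + 1L
      out_coords[, , isnap] <- x
      out$times[isnap] <- t_end
      out$cc[isnap] <- ev$cc
      out$vfit[isnap] <- ev$vfit
      out$vff[isnap] <- ev$vff
      out$t_target[isnap] <- temp_at(thermostat, t_end)
    }
  }
  structure(list(times = out$times, coords = out_coords, cc = out$cc,
                 vfit = out$vfit, vff = out$vff, t_target = out$t_target,
                 stride = as.integer(stride), dt = dt,
                 final_coords = x, final_velocities = v),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d snapshots over %.4g..%.4g ps (dt = %g ps)\n",
              length(x$times), min(x$times), max(x$times), x$dt))
  invisible(x)
}

#' Export a trajectory as a multi-model PDB plus a CSV of scalars
#'
#' @param traj a `trajectory`.
#' @param model the [atomic_model] providing atom metadata.
#' @param pdb_path multi-model PDB output path (NULL to skip).
#' @param csv_path per-snapshot scalar CSV output path (NULL to skip).
#' @return Invisibly, the data frame of per-snapshot scalars.
#' @export
export_trajectory <- function(traj, model, pdb_path = NULL, csv_path = NULL) {
  scalars <- data.frame(time = traj$times, cc = traj$cc, vfit = traj$vfit,
                        vff = traj$vff, t_target = traj$t_target)
  if (!is.null(csv_path)) write.csv(scalars, csv_path, row.names = FALSE)
  if (!is.null(pdb_path)) {
    tmp <- tempfile(fileext = ".pdb")
    con <- file(pdb_path, "w")
    on.exit(close(con))
    for (s in seq_along(traj$times)) {
      writeLines(sprintf("MODEL     %4d", s), con)
      write_model(set_coords(model, traj$coords[, , s]), tmp)
      lines <- readLines(tmp)
      writeLines(grep("^(ATOM|HETATM|TER)", lines, value = TRUE), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
    unlink(tmp)
  }
  invisible(scalars)
}
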