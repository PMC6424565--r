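# The correlation biasing potential: Vfit = k (1 - c.c.), where c.c. is the
# cosine similarity between the experimental and the simulated density over
# all voxels (no mean subtraction, no mask), so negative densities contribute
# with sign. Forces are the exact analytic negative gradient of Vfit with
# respect to the masked atoms' coordinates; both the cross term and the
# simulated-map normalization self-term of the c.c. quotient contribute.

#' Real-space correlation coefficient between two maps
#'
#' `cc = sum(a*b) / sqrt(sum(a^2) * sum(b^2))` over all voxels. With
#' `pearson = TRUE` the voxel means are subtracted first (non-default
#' variant).
#'
#' @param a,b `density_map` objects on identical grids; neither all zero.
#' @param pearson subtract voxel means before correlating (default FALSE).
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
map_correlation <- function(a, b, pearson = FALSE) {
  assert_same_grid(a, b)
  va <- as.numeric(a$values); vb <- as.numeric(b$values)
  if (pearson) { va <- va - mean(va); vb <- vb - mean(vb) }
  denom2 <- sum(va * va) * sum(vb * vb)
  if (denom2 < 1e-60)
    stop("correlation undefined: map '",
         if (sum(va * va) <= sum(vb * vb)) a$label else b$label,
         "' has (near-)zero norm")
  sum(va * vb) / sqrt(denom2)
}

#' Biasing energy and analytic forces of the fitting potential
#'
#' Spreads the masked atoms onto the grid of `exp_map` at width
#' `params$sigma`, computes `cc`, the energy `k * (1 - cc)` and the exact
#' analytic forces (kJ mol^-1 nm^-1). Atoms outside the fit mask have
#' exactly zero force.
#'
#' @param model an [atomic_model].
#' @param exp_map experimental [density_map] (nonzero).
#' @param k force constant in kJ mol^-1 (>= 0); `k = 0` gives zero energy
#'   and forces (cc is still reported).
#' @param params a [spread_params].
#' @return An object of class `fit_state`: list with `k`, `sigma`, `cc`,
#'   `energy`, `forces` (n x 3), and `sim` (the simulated map).
#' @export
fit_energy_forces <- function(model, exp_map, k, params) {
  stopifnot(inherits(params, "spread_params"))
  if (k < 0) stop("k must be >= 0")
  sigma_ang <- params$sigma * ANGSTROM_PER_NM
  sel <- model$fit_mask
  if (!any(sel)) stop("no atoms in fit mask")
  w <- effective_weights(model, params$weight_mode)[sel]
  coords_ang <- model$coords[sel, , drop = FALSE] * ANGSTROM_PER_NM
  d <- dim(exp_map$values)
  ve <- as.numeric(exp_map$values)
  kern <- fit_kernel_cpp(coords_ang, w, ve, as.integer(d),
                         exp_map$voxel_size, exp_map$origin, sigma_ang,
                         params$cutoff_multiplier, k > 0)
  sim <- kern$sim
  s_aa <- sum(ve * ve); s_bb <- sum(sim * sim)
  if (s_aa < 1e-30) stop("correlation undefined: experimental map has zero norm")
  if (s_bb < 1e-30) stop("correlation undefined: simulated map has zero norm (atoms outside grid?)")
  s_ab <- sum(ve * sim)
  cc <- s_ab / sqrt(s_aa * s_bb)
  forces <- matrix(0, nrow = n_atoms(model), ncol = 3)
  if (k > 0) {
    terms <- kern
    inv_s2 <- 1 / (sigma_ang^2)
    dcc <- (terms$A * inv_s2) / sqrt(s_aa * s_bb) -
      cc * (terms$B * inv_s2) / s_bb
    # d cc / d x is per Angstrom; force = -dVfit/dx = +k dcc/dx, per nm
    forces[sel, ] <- k * dcc * ANGSTROM_PER_NM
  }
  structure(list(k = k, sigma = params$sigma, cc = cc,
                 energy = k * (1 - cc), forces = forces,
                 sim = density_map(array(sim, dim = d), exp_map$voxel_size,
                                   exp_map$origin, label = "simulated")),
            class = "fit_state")
}

#' @export
print.fit_state <- function(x, ...) {
  cat(sprintf("fit_state: k = %.4g kJ/mol, sigma = %.3g nm, cc = %.6f, Vfit = %.6g kJ/mol, max|F| = %.4g kJ/mol/nm\n",
              x$k, x$sigma, x$cc, x$energy, max(abs(x$forces))))
  invisible(x)
}

#' Force provider for the fitting potential
#'
#' Wraps [fit_energy_forces] into the engine's force-provider contract:
#' a function `(coords, time) -> list(energy, forces, cc)`. The force
#' constant and width may be [parameter_schedule]s evaluated at `time`, or
#' constants.
#'
#' @param exp_map experimental [density_map].
#' @param k force constant (kJ mol^-1) or a schedule of it.
#' @param sigma Gaussian width (nm) or a schedule of it.
#' @param template_model the [atomic_model] whose metadata (mask, weights)
#'   the provider uses; coordinates are supplied per call.
#' @param cutoff_multiplier,weight_mode passed to [spread_params].
#' @return A provider function with attribute `role = "fit"`.
#' @export
fit_provider <- function(exp_map, k, sigma, template_model,
                         cutoff_multiplier = 4,
                         weight_mode = "atomic_number") {
  f <- function(coords, time = 0) {
    kt <- if (inherits(k, "parameter_schedule")) schedule_value(k, time) else k
    st <- if (inherits(sigma, "parameter_schedule"))
      schedule_value(sigma, time) else sigma
    st_model <- set_coords(template_model, coords)
    fs <- fit_energy_forces(st_model, exp_map, kt,
                            spread_params(st, cutoff_multiplier, weight_mode))
    list(energy = fs$energy, forces = fs$forces, cc = fs$cc, k = kt,
         sigma = st)
  }
  attr(f, "role") <- "fit"
  f
}
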