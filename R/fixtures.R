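# Synthetic fixtures: toy polymers built at mechanical equilibrium,
# ground-truth maps produced by Gaussian spreading at a known sigma, and
# half-map pairs with independent noise realizations. Everything is
# deterministic per seed, so every other module is testable without
# downloads.

#' Fixture specification
#'
#' @param n_atoms chain length (>= 3; default 20).
#' @param b0 bond length, nm (default 0.38, a C-alpha virtual bond).
#' @param kb bond stiffness, kJ mol^-1 nm^-2 (default 5e4).
#' @param ktheta angle stiffness, kJ mol^-1 rad^-2 (default 400).
#' @param geometry `"helix"` or `"random-walk"`.
#' @param map_dims voxel counts (default 24^3).
#' @param voxel_size voxel spacing, Angstrom (default 2).
#' @param sigma_true generating Gaussian width, nm (default 0.2).
#' @param noise_sd half-map noise standard deviation as a fraction of the
#'   ground-truth map RMS (default 0).
#' @param noise_correlation Gaussian correlation length of the noise in
#'   voxels (0 = white noise; > 0 gives band-limited noise for overfitting
#'   controls).
#' @param seed integer seed.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_atoms = 20, b0 = 0.38, kb = 5e4, ktheta = 400,
                         geometry = c("helix", "random-walk"),
                         map_dims = c(24, 24, 24), voxel_size = 2,
                         sigma_true = 0.2, noise_sd = 0,
                         noise_correlation = 0, seed = 1) {
  geometry <- match.arg(geometry)
  if (n_atoms < 3) stop("n_atoms must be >= 3")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (b0 <= 0 || sigma_true <= 0) stop("b0 and sigma_true must be > 0")
  structure(list(n_atoms = as.integer(n_atoms), b0 = b0, kb = kb,
                 ktheta = ktheta, geometry = geometry,
                 map_dims = as.integer(rep_len(map_dims, 3)),
                 voxel_size = rep_len(as.numeric(voxel_size), 3),
                 sigma_true = sigma_true, noise_sd = noise_sd,
                 noise_correlation = noise_correlation,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Build a toy polymer at mechanical equilibrium
#'
#' `"helix"` places atoms on a regular helix whose chord equals `b0`, so all
#' bonds and angles are exactly at their equilibrium values. `"random-walk"`
#' grows a chain with fixed bond length and random bend angles, rejecting
#' steric overlaps; per-angle equilibrium values are set to the constructed
#' geometry, so the fresh polymer has zero energy and forces either way.
#'
#' @param spec a [fixture_spec].
#' @return List with `model` ([atomic_model]) and `topo` ([toy_topology]).
#' @export
make_toy_polymer <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_atoms
  b0 <- spec$b0
  r_min <- 0.3  # soft-core onset, nm; below every non-bonded contact
  if (spec$geometry == "helix") {
    radius <- 0.5
    pitch_frac <- 0.35  # axial rise as a fraction of the chord
    rise <- b0 * pitch_frac
    chord_xy <- sqrt(b0^2 - rise^2)
    dphi <- 2 * asin(chord_xy / (2 * radius))
    phi <- (0:(n - 1)) * dphi
    coords <- cbind(radius * cos(phi), radius * sin(phi),
                    (0:(n - 1)) * rise)
  } else {
    set.seed(spec$seed)
    coords <- matrix(0, n, 3)
    dir <- c(1, 0, 0)
    coords[2, ] <- coords[1, ] + b0 * dir
    for (i in 3:n) {
      repeat {
        bend <- runif(1, 0.5, 1.2)    # rad, away from straight
        azim <- runif(1, 0, 2 * pi)
        # rotate previous direction by bend about a random perpendicular
        perp1 <- pracma_nullspace(dir)
        newdir <- cos(bend) * dir +
          sin(bend) * (cos(azim) * perp1[, 1] + sin(azim) * perp1[, 2])
        cand <- coords[i - 1, ] + b0 * newdir
        d2 <- rowSums((coords[seq_len(i - 2), , drop = FALSE] -
                         matrix(cand, i - 2, 3, byrow = TRUE))^2)
        if (all(d2 > r_min^2)) break
      }
      coords[i, ] <- cand
      dir <- newdir
    }
  }
  coords <- sweep(coords, 2, colMeans(coords))  # center at the origin
  model <- atomic_model(coords, masses = 12, element = "C",
                        resno = seq_len(n), resid = "ALA", chain = "A")
  bonds <- data.frame(i = 1:(n - 1), j = 2:n, b0 = b0, kb = spec$kb)
  # equilibrium angles from the constructed geometry
  ai <- 1:(n - 2); aj <- 2:(n - 1); ak <- 3:n
  v1 <- coords[ai, , drop = FALSE] - coords[aj, , drop = FALSE]
  v2 <- coords[ak, , drop = FALSE] - coords[aj, , drop = FALSE]
  cth <- rowSums(v1 * v2) / (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
  theta0 <- acos(pmin(pmax(cth, -1), 1))
  angles <- data.frame(i = ai, j = aj, k = ak, theta0 = theta0,
                       ktheta = spec$ktheta)
  topo <- toy_topology(bonds, angles,
                       repulsion = list(cutoff = 1.0, eps = 50,
                                        r_min = r_min),
                       n_atoms = n)
  list(model = model, topo = topo)
}

# two unit vectors perpendicular to v
pracma_nullspace <- function(v) {
  v <- v / sqrt(sum(v^2))
  a <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p1 <- a - sum(a * v) * v
  p1 <- p1 / sqrt(sum(p1^2))
  p2 <- c(v[2] * p1[3] - v[3] * p1[2],
          v[3] * p1[1] - v[1] * p1[3],
          v[1] * p1[2] - v[2] * p1[1])
  cbind(p1, p2)
}

#' Grid template centered on a model
#'
#' @param model an [atomic_model].
#' @param spec a [fixture_spec] providing dims and voxel size.
#' @return An all-zero [density_map] centered on the model centroid.
#' @export
fixture_grid <- function(model, spec) {
  centroid <- colMeans(model$coords) * ANGSTROM_PER_NM
  origin <- centroid - (spec$map_dims - 1) / 2 * spec$voxel_size
  density_map(array(0, dim = spec$map_dims), spec$voxel_size, origin,
              label = "template")
}

# white or band-limited Gaussian noise field, unit variance
noise_field <- function(dims, correlation) {
  eta <- array(rnorm(prod(dims)), dim = dims)
  if (correlation > 0) {
    # Gaussian smoothing via FFT, then re-normalize to unit variance
    gk <- lapply(1:3, function(a) {
      k <- c(0:floor((dims[a] - 1) / 2), -(ceiling((dims[a] - 1) / 2):1))
      exp(-2 * (pi * k / dims[a] * correlation)^2)
    })
    filt <- outer(outer(gk[[1]], gk[[2]]), gk[[3]])
    eta <- Re(fft(fft(eta) * filt, inverse = TRUE)) / prod(dims)
    eta <- eta / sd(as.numeric(eta))
  }
  eta
}

#' Ground-truth map and half-map pair for a model
#'
#' The ground truth is the model spread at `sigma_true`; each half-map adds
#' an independent noise realization with standard deviation
#' `noise_sd * RMS(truth)` (optionally band-limited); the full map is the
#' average of the two half-maps. Noise seeds are derived from `spec$seed`.
#'
#' @param model an [atomic_model].
#' @param spec a [fixture_spec].
#' @param template optional [density_map] grid (default: [fixture_grid]).
#' @return List with `truth`, `half1`, `half2`, `full` ([density_map]s).
#' @export
make_ground_truth_maps <- function(model, spec, template = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (is.null(template)) template <- fixture_grid(model, spec)
  truth <- spread_atoms(model, template,
                        spread_params(spec$sigma_true, 4, "atomic_number"))
  truth$label <- "truth"
  if (spec$noise_sd == 0) {
    half1 <- truth; half1$label <- "half1"
    half2 <- truth; half2$label <- "half2"
    full <- truth; full$label <- "full"
    return(list(truth = truth, half1 = half1, half2 = half2, full = full))
  }
  rms <- sqrt(mean(truth$values^2))
  d <- dim(truth$values)
  set.seed(spec$seed + 1L)
  n1 <- noise_field(d, spec$noise_correlation) * spec$noise_sd * rms
  set.seed(spec$seed + 2L)
  n2 <- noise_field(d, spec$noise_correlation) * spec$noise_sd * rms
  half1 <- density_map(truth$values + n1, truth$voxel_size, truth$origin,
                       "half1")
  half2 <- density_map(truth$values + n2, truth$voxel_size, truth$origin,
                       "half2")
  full <- density_map((half1$values + half2$values) / 2, truth$voxel_size,
                      truth$origin, "full")
  list(truth = truth, half1 = half1, half2 = half2, full = full)
}

#' Perturb a model away from its current configuration
#'
#' `"thermal-like"` applies a chain-correlated random displacement field
#' rescaled so the RMSD from the input equals `magnitude` exactly.
#' `"domain-hinge"` rigidly rotates the second half of the chain about an
#' axis through the chain midpoint, with the rotation angle solved so the
#' RMSD matches `magnitude`; bond lengths within the rotated block are
#' preserved exactly.
#'
#' @param model an [atomic_model].
#' @param magnitude target RMSD from the input, nm (>= 0).
#' @param mode `"thermal-like"` or `"domain-hinge"`.
#' @param seed integer seed.
#' @return The perturbed [atomic_model].
#' @export
perturb_model <- function(model, magnitude, mode = c("thermal-like",
                                                     "domain-hinge"),
                          seed = 1) {
  mode <- match.arg(mode)
  if (magnitude < 0) stop("magnitude must be >= 0")
  if (magnitude == 0) return(model)
  x <- model$coords
  n <- nrow(x)
  set.seed(seed)
  if (mode == "thermal-like") {
    # random displacement smoothed along the chain index (correlation
    # length ~ n/5 atoms), then rescaled to the exact target RMSD
    raw <- matrix(rnorm(3 * n), n, 3)
    L <- max(2, round(n / 5))
    kern <- dnorm(seq(-3, 3, length.out = 2 * L + 1))
    kern <- kern / sum(kern)
    sm <- apply(raw, 2, function(col) {
      padded <- c(rep(col[1], L), col, rep(col[n], L))
      as.numeric(stats::filter(padded, kern, sides = 2))[(L + 1):(L + n)]
    })
    sm <- sweep(sm, 2, colMeans(sm))
    scale <- magnitude / sqrt(mean(rowSums(sm^2)))
    out <- x + sm * scale
  } else {
    half <- floor(n / 2)
    pivot <- (x[half, ] + x[half + 1, ]) / 2
    axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
    rot_block <- function(angle) {
      R <- rotation_matrix(axis, angle)
      y <- x
      blk <- (half + 1):n
      y[blk, ] <- sweep(sweep(x[blk, , drop = FALSE], 2, pivot) %*% t(R),
                        2, pivot, `+`)
      y
    }
    rmsd_of <- function(angle)
      sqrt(mean(rowSums((rot_block(angle) - x)^2)))
    if (rmsd_of(pi) < magnitude)
      stop(sprintf("magnitude %.3g nm unreachable by hinge rotation (max %.3g nm)",
                   magnitude, rmsd_of(pi)))
    ang <- stats::uniroot(function(a) rmsd_of(a) - magnitude,
                          c(0, pi), tol = 1e-10)$root
    out <- rot_block(ang)
  }
  set_coords(model, out)
}

rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle); C <- 1 - c_
  matrix(c(
    a[1] * a[1] * C + c_,        a[1] * a[2] * C - a[3] * s_, a[1] * a[3] * C + a[2] * s_,
    a[2] * a[1] * C + a[3] * s_, a[2] * a[2] * C + c_,        a[2] * a[3] * C - a[1] * s_,
    a[3] * a[1] * C - a[2] * s_, a[3] * a[2] * C + a[1] * s_, a[3] * a[3] * C + c_),
    3, 3, byrow = TRUE)
}

#' Write a complete fixture set to a directory
#'
#' @param spec a [fixture_spec].
#' @param dir output directory (created if needed).
#' @return Invisibly, the list of generated objects.
#' @export
write_fixture <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  px <- make_toy_polymer(spec)
  maps <- make_ground_truth_maps(px$model, spec)
  write_model(px$model, file.path(dir, "model.pdb"))
  jsonlite::write_json(
    list(bonds = px$topo$bonds, angles = px$topo$angles,
         repulsion = px$topo$repulsion, n_atoms = px$topo$n_atoms),
    file.path(dir, "topology.json"), digits = NA, auto_unbox = TRUE)
  for (nm in names(maps))
    write_map(maps[[nm]], file.path(dir, paste0(nm, ".mrc")))
  invisible(c(px, maps))
}

#' Read a toy topology written by [write_fixture]
#' @param path path to `topology.json`.
#' @return A [toy_topology].
#' @export
read_topology <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  toy_topology(as.data.frame(j$bonds),
               if (!is.null(j$angles)) as.data.frame(j$angles),
               as.list(j$repulsion), n_atoms = j$n_atoms)
}
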