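# Shared synthetic fixtures, built in code (no binary files). Cached per
# parameter set so repeated tests don't regenerate maps.

.fixture_cache <- new.env(parent = emptyenv())

std_fixture <- function(noise_sd = 0, noise_correlation = 0, seed = 7,
                        n_atoms = 20, dims = 24, geometry = "helix") {
  key <- paste(noise_sd, noise_correlation, seed, n_atoms, dims, geometry,
               sep = "|")
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  spec <- fixture_spec(n_atoms = n_atoms, map_dims = rep(dims, 3),
                       geometry = geometry, noise_sd = noise_sd,
                       noise_correlation = noise_correlation, seed = seed)
  px <- make_toy_polymer(spec)
  maps <- make_ground_truth_maps(px$model, spec)
  out <- c(px, maps, list(spec = spec))
  .fixture_cache[[key]] <- out
  out
}

# small map with given values (recycled) on a default grid
small_map <- function(vals, dims = c(4, 4, 4), vox = 2, origin = c(0, 0, 0),
                      label = "test") {
  density_map(array(rep_len(vals, prod(dims)), dim = dims), vox, origin,
              label)
}

# central finite-difference forces of a provider-style energy function
fd_forces <- function(energy_fn, coords, h = 1e-5, atoms = NULL) {
  if (is.null(atoms)) atoms <- seq_len(nrow(coords))
  out <- matrix(NA_real_, nrow(coords), 3)
  for (a in atoms) for (c3 in 1:3) {
    xp <- coords; xp[a, c3] <- xp[a, c3] + h
    xm <- coords; xm[a, c3] <- xm[a, c3] - h
    out[a, c3] <- -(energy_fn(xp) - energy_fn(xm)) / (2 * h)
  }
  out
}
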