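# The correlation coefficient, the biasing energy Vfit = k (1 - cc) and its
# analytic forces. The finite-difference oracle is the ground truth for the
# gradient; a brute-force untruncated double loop cross-checks the
# truncated kernel.

test_that("correlation identities and the hand-computed cosine example", {
  m <- small_map(rnorm(64), dims = c(4, 4, 4))
  expect_equal(map_correlation(m, m), 1.0, tolerance = 1e-12)
  neg <- m; neg$values <- -neg$values
  expect_equal(map_correlation(m, neg), -1.0, tolerance = 1e-12)
  # a = single unit voxel, b = the same voxel plus one more: cos = 1/sqrt(2)
  a <- small_map(0, dims = c(2, 2, 2)); a$values[1, 1, 1] <- 1
  b <- small_map(0, dims = c(2, 2, 2)); b$values[1, 1, 1] <- 1
  b$values[2, 1, 1] <- 1
  expect_equal(map_correlation(a, b), 1 / sqrt(2), tolerance = 1e-12)
})

test_that("correlation rejects mismatched grids and zero-norm maps", {
  a <- small_map(1, dims = c(4, 4, 4))
  b <- small_map(1, dims = c(4, 4, 5))
  expect_error(map_correlation(a, b), "grid mismatch")
  shifted <- small_map(1, dims = c(4, 4, 4), origin = c(1, 0, 0))
  expect_error(map_correlation(a, shifted), "grid mismatch")
  zero <- small_map(0, dims = c(4, 4, 4))
  expect_error(map_correlation(a, zero), "zero norm")
})

test_that("cc is scale invariant and forces scale linearly with k", {
  fx <- std_fixture()
  pm <- perturb_model(fx$model, 0.2, "thermal-like", seed = 3)
  p <- spread_params(0.2)
  f1 <- fit_energy_forces(pm, fx$truth, 1e4, p)
  scaled <- fx$truth; scaled$values <- scaled$values * 37.5
  f2 <- fit_energy_forces(pm, scaled, 1e4, p)
  expect_equal(f1$cc, f2$cc, tolerance = 1e-12)
  f3 <- fit_energy_forces(pm, fx$truth, 3e4, p)
  expect_equal(f3$forces, 3 * f1$forces, tolerance = 1e-12)
  expect_equal(f3$energy, 3 * f1$energy, tolerance = 1e-12)
})

test_that("noiseless self-map is a stationary point: cc = 1, forces vanish", {
  fx <- std_fixture()
  k <- 1e5
  fs <- fit_energy_forces(fx$model, fx$truth, k, spread_params(0.2))
  expect_equal(fs$cc, 1.0, tolerance = 1e-9)
  expect_equal(fs$energy, k * (1 - fs$cc), tolerance = 1e-9)
  expect_lt(max(abs(fs$forces)), 1e-6 * k)
})

test_that("k = 0 gives zero energy and forces but still reports cc", {
  fx <- std_fixture()
  pm <- perturb_model(fx$model, 0.3, "thermal-like", seed = 4)
  fs <- fit_energy_forces(pm, fx$truth, 0, spread_params(0.2))
  expect_identical(fs$energy, 0)
  expect_true(all(fs$forces == 0))
  expect_true(fs$cc < 1 && fs$cc > -1)
})

test_that("analytic forces match central finite differences", {
  fx <- std_fixture()
  pm <- perturb_model(fx$model, 0.25, "thermal-like", seed = 9)
  k <- 1e5; p <- spread_params(0.2)
  fs <- fit_energy_forces(pm, fx$truth, k, p)
  efun <- function(x) fit_energy_forces(set_coords(pm, x), fx$truth, k,
                                        p)$energy
  atoms <- c(1, 5, 10, 20)
  fd <- fd_forces(efun, pm$coords, h = 1e-5, atoms = atoms)
  rel <- abs(fd[atoms, ] - fs$forces[atoms, ]) /
    pmax(abs(fd[atoms, ]), abs(fs$forces[atoms, ]), 1e-8)
  expect_lt(max(rel), 1e-4)
})

test_that("non-masked atoms get exactly zero force", {
  fx <- std_fixture()
  pm <- perturb_model(fx$model, 0.2, "thermal-like", seed = 5)
  pm$fit_mask[c(3, 7)] <- FALSE
  fs <- fit_energy_forces(pm, fx$truth, 1e5, spread_params(0.2))
  expect_identical(fs$forces[3, ], c(0, 0, 0))
  expect_identical(fs$forces[7, ], c(0, 0, 0))
  expect_gt(max(abs(fs$forces)), 0)
})

test_that("the field is conservative: a small step along the force lowers the energy", {
  fx <- std_fixture()
  for (seed in 1:3) {
    pm <- perturb_model(fx$model, 0.3, "thermal-like", seed = seed)
    fs <- fit_energy_forces(pm, fx$truth, 1e5, spread_params(0.2))
    fmax <- max(abs(fs$forces))
    step <- 1e-5 / fmax
    moved <- set_coords(pm, pm$coords + fs$forces * step)
    fs2 <- fit_energy_forces(moved, fx$truth, 1e5, spread_params(0.2))
    expect_lt(fs2$energy, fs$energy)
  }
})

test_that("truncated kernel agrees with an untruncated brute-force double loop", {
  # tiny instance: 5 atoms, 10^3 voxels, direct R evaluation over all
  # (atom, voxel) pairs with no cutoff
  spec <- fixture_spec(n_atoms = 5, map_dims = c(10, 10, 10), seed = 21)
  px <- make_toy_polymer(spec)
  tmpl <- fixture_grid(px$model, spec)
  truth <- spread_atoms(px$model, tmpl, spread_params(0.2, 8))
  pm <- perturb_model(px$model, 0.15, "thermal-like", seed = 2)
  k <- 1e4; sigma <- 0.2
  fs <- fit_energy_forces(pm, truth, k, spread_params(sigma))

  d <- dim(truth$values)
  grid <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                                k = 0:(d[3] - 1)))
  vpos <- sweep(sweep(grid, 2, truth$voxel_size, `*`), 2, truth$origin, `+`)
  sig_a <- sigma * ANGSTROM_PER_NM
  xa <- pm$coords * ANGSTROM_PER_NM
  w <- effective_weights(pm, "atomic_number")
  gmat <- sapply(seq_len(nrow(xa)), function(a)
    w[a] * exp(-rowSums(sweep(vpos, 2, xa[a, ])^2) / (2 * sig_a^2)))
  sim <- rowSums(gmat)
  ve <- as.numeric(truth$values)
  s_ab <- sum(ve * sim); s_aa <- sum(ve^2); s_bb <- sum(sim^2)
  cc_bf <- s_ab / sqrt(s_aa * s_bb)
  expect_equal(fs$cc, cc_bf, tolerance = 1e-3)
  forces_bf <- t(sapply(seq_len(nrow(xa)), function(a) {
    dxyz <- sweep(vpos, 2, xa[a, ])      # x_v - x_a, Angstrom
    A <- colSums(dxyz * (ve * gmat[, a]))
    B <- colSums(dxyz * (sim * gmat[, a]))
    dcc <- (A / sig_a^2) / sqrt(s_aa * s_bb) - cc_bf * (B / sig_a^2) / s_bb
    k * dcc * ANGSTROM_PER_NM
  }))
  rel <- sqrt(sum((fs$forces - forces_bf)^2)) / sqrt(sum(forces_bf^2))
  expect_lt(rel, 1e-3)
})

test_that("fit_provider evaluates schedules at the requested time", {
  fx <- std_fixture()
  ks <- parameter_schedule(c(0, 10), c(1e4, 5e4), "kJ/mol")
  ss <- parameter_schedule(c(0, 10), c(0.6, 0.2), "nm")
  fp <- fit_provider(fx$truth, ks, ss, fx$model)
  r0 <- fp(fx$model$coords, 0)
  r5 <- fp(fx$model$coords, 5)
  expect_equal(r0$k, 1e4); expect_equal(r0$sigma, 0.6)
  expect_equal(r5$k, 3e4); expect_equal(r5$sigma, 0.4)
})

test_that("the merged spread+gradient kernel equals the two-pass reference", {
  fx <- std_fixture()
  pm <- perturb_model(fx$model, 0.3, "thermal-like", seed = 4)
  coords_ang <- pm$coords * ANGSTROM_PER_NM
  w <- effective_weights(pm)
  d <- dim(fx$truth$values)
  ve <- as.numeric(fx$truth$values)
  vox <- fx$truth$voxel_size; org <- fx$truth$origin
  sim <- cdfit:::spread_density_cpp(coords_ang, w, as.integer(d), vox, org,
                                    2, 4)
  ref <- cdfit:::cc_gradient_terms_cpp(coords_ang, w, ve, sim,
                                       as.integer(d), vox, org, 2, 4)
  merged <- cdfit:::fit_kernel_cpp(coords_ang, w, ve, as.integer(d), vox,
                                   org, 2, 4, TRUE)
  expect_identical(merged$sim, sim)
  expect_identical(merged$A, ref$A)
  expect_identical(merged$B, ref$B)
})
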