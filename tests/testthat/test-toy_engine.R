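# The minimal bonded force field, the steepest-descent minimizer and the
# Langevin (BAOAB) integrator.

single_bond <- function(b0 = 0.38, kb = 5e4, stretch = 0) {
  coords <- matrix(c(0, 0, 0, b0 + stretch, 0, 0), 2, 3, byrow = TRUE)
  list(model = atomic_model(coords, masses = 12),
       topo = toy_topology(data.frame(i = 1, j = 2, b0 = b0, kb = kb)))
}

test_that("equilibrium geometry has zero energy and forces", {
  fx <- std_fixture()
  ef <- toy_energy_forces(fx$model, fx$topo)
  expect_lt(abs(ef$energy), 1e-9)
  expect_lt(max(abs(ef$forces)), 1e-6)
})

test_that("a stretched bond follows the closed-form harmonic law", {
  delta <- 0.07; kb <- 5e4
  sb <- single_bond(stretch = delta, kb = kb)
  ef <- toy_energy_forces(sb$model, sb$topo)
  expect_equal(ef$energy, 0.5 * kb * delta^2, tolerance = 1e-12)
  expect_equal(sqrt(sum(ef$forces[1, ]^2)), kb * delta, tolerance = 1e-9)
  expect_equal(ef$forces[1, ], -ef$forces[2, ], tolerance = 1e-12)
})

test_that("toy forces match central finite differences on a random configuration", {
  fx <- std_fixture()
  set.seed(31)
  x <- fx$model$coords + matrix(rnorm(3 * n_atoms(fx$model), sd = 0.04),
                                ncol = 3)
  ef <- toy_energy_forces(x, fx$topo)
  fd <- fd_forces(function(y) toy_energy_forces(y, fx$topo)$energy, x,
                  h = 1e-6, atoms = c(1, 4, 9, 15, 20))
  sel <- c(1, 4, 9, 15, 20)
  rel <- abs(fd[sel, ] - ef$forces[sel, ]) /
    pmax(abs(fd[sel, ]), abs(ef$forces[sel, ]), 1e-4)
  expect_lt(max(rel), 1e-6)
})

test_that("topology validation catches bad indices and self-bonds", {
  expect_error(toy_topology(data.frame(i = 1, j = 1, b0 = 0.3, kb = 1)),
               "self-bonds")
  expect_error(toy_topology(data.frame(i = 1, j = 5, b0 = 0.3, kb = 1),
                            n_atoms = 3), "out of range")
  topo <- toy_topology(data.frame(i = 1, j = 2, b0 = 0.3, kb = 1))
  expect_error(toy_energy_forces(matrix(0, 1, 3), topo), "out of range")
})

test_that("minimizer returns an input already at a minimum unchanged", {
  fx <- std_fixture()
  out <- minimize(fx$model, list(toy_provider(fx$topo)), tol = 1e-3)
  expect_identical(out$coords, fx$model$coords)
  expect_identical(attr(out, "steps"), 0L)
})

test_that("minimizer relaxes a stretched bond to b0", {
  sb <- single_bond(stretch = 0.15)
  out <- minimize(sb$model, list(toy_provider(sb$topo)), tol = 1e-4,
                  max_steps = 5000)
  blen <- sqrt(sum((out$coords[2, ] - out$coords[1, ])^2))
  expect_equal(blen, 0.38, tolerance = 1e-6)
})

test_that("minimizing under the fitting potential alone strictly increases cc", {
  fx <- std_fixture()
  pm <- perturb_model(fx$model, 0.3, "thermal-like", seed = 8)
  fp <- fit_provider(fx$truth, 1e5, 0.25, pm)
  cc0 <- fp(pm$coords, 0)$cc
  out <- minimize(pm, list(fp), max_steps = 200, tol = 1e-2)
  cc1 <- fp(out$coords, 0)$cc
  expect_gt(cc1, cc0)
  expect_gt(attr(out, "steps"), 0)
})

test_that("zero forces at T = 0 leave coordinates unchanged", {
  sb <- single_bond()  # at equilibrium: zero forces
  th <- thermostat_schedule(0, 0, friction = 5, seed = 1)
  traj <- integrate_langevin(sb$model, list(toy_provider(sb$topo)), th,
                             dt = 0.002, n_steps = 200, stride = 50)
  for (s in seq_along(traj$times))
    expect_equal(traj$coords[, , s], sb$model$coords, tolerance = 1e-12)
})

test_that("trajectories are bitwise reproducible per seed and differ across seeds", {
  fx <- std_fixture()
  prov <- list(toy_provider(fx$topo))
  th1 <- thermostat_schedule(0, 150, friction = 5, seed = 99)
  t1 <- integrate_langevin(fx$model, prov, th1, 0.002, 300, stride = 100)
  t2 <- integrate_langevin(fx$model, prov, th1, 0.002, 300, stride = 100)
  expect_identical(t1$coords, t2$coords)
  th2 <- thermostat_schedule(0, 150, friction = 5, seed = 100)
  t3 <- integrate_langevin(fx$model, prov, th2, 0.002, 300, stride = 100)
  expect_false(identical(t1$coords, t3$coords))
})

test_that("a thermostatted bond satisfies equipartition within sampling error", {
  sb <- single_bond()
  th <- thermostat_schedule(0, 100, friction = 20, seed = 123)
  traj <- integrate_langevin(sb$model, list(toy_provider(sb$topo)), th,
                             dt = 0.002, n_steps = 50000, stride = 10)
  # discard 10% burn-in; mean harmonic bond energy ~ kT/2 (1 effective dof)
  keep <- traj$times > 0.1 * max(traj$times)
  mean_v <- mean(traj$vff[keep])
  kT2 <- 0.5 * 0.0083144621 * 100
  expect_lt(abs(mean_v - kT2) / kT2, 0.15)
})

test_that("center of mass does not drift at T = 0 under bonded forces only", {
  sb <- single_bond(stretch = 0.1)
  th <- thermostat_schedule(0, 0, friction = 5, seed = 1)
  traj <- integrate_langevin(sb$model, list(toy_provider(sb$topo)), th,
                             dt = 0.002, n_steps = 500, stride = 100)
  com0 <- colMeans(sb$model$coords)
  for (s in seq_along(traj$times))
    expect_equal(colMeans(traj$coords[, , s]), com0, tolerance = 1e-10)
})

test_that("snapshot energies equal fresh recomputation from coordinates", {
  fx <- std_fixture()
  prov <- list(toy_provider(fx$topo),
               fit_provider(fx$truth, 2e4, 0.25, fx$model))
  th <- thermostat_schedule(0, 100, friction = 5, seed = 17)
  traj <- integrate_langevin(fx$model, prov, th, 0.002, 200, stride = 50)
  for (s in seq_along(traj$times)) {
    x <- traj$coords[, , s]
    expect_equal(traj$vff[s], toy_energy_forces(x, fx$topo)$energy,
                 tolerance = 1e-9)
    fs <- fit_energy_forces(set_coords(fx$model, x), fx$truth, 2e4,
                            spread_params(0.25))
    expect_equal(traj$vfit[s], fs$energy, tolerance = 1e-9)
    expect_equal(traj$cc[s], fs$cc, tolerance = 1e-9)
  }
})

test_that("an unstable integration aborts with step context", {
  sb <- single_bond(stretch = 0.2)
  th <- thermostat_schedule(0, 100, friction = 5, seed = 1)
  expect_warning(
    expect_error(
      integrate_langevin(sb$model, list(toy_provider(sb$topo)), th,
                         dt = 5, n_steps = 500, stride = 100,
                         topo = sb$topo),
      class = "cdfit_instability"),
    "unstable")
})
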