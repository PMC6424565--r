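# Refinement protocol: schedules, final-model averaging, the k sweep and
# null controls. Full recovery and overfitting experiments live in the
# acceptance tests.

test_that("default protocol reproduces the published schedule shape", {
  cfg <- default_protocol(sigma_stop = 0.2, k_stop = 5e5,
                          variant = "100K/50")
  # hold at sigma_start for the first 3 ps of 50, then linear ramp
  expect_equal(schedule_value(cfg$sigma_schedule, 0), 0.6)
  expect_equal(schedule_value(cfg$sigma_schedule, 3), 0.6)
  expect_equal(schedule_value(cfg$sigma_schedule, 50), 0.2)
  expect_equal(schedule_value(cfg$k_schedule, 0), 0.5e5)
  expect_equal(schedule_value(cfg$k_schedule, 3), 0.5e5)
  # linear midpoint of the ramp [3, 50]: t = 26.5, k: 0.5e5 -> 5e5
  expect_equal(schedule_value(cfg$k_schedule, 26.5), 2.75e5)
  # stage 2 holds sigma_stop and k_stop constant throughout
  for (t in c(50, 55, 62, 70)) {
    expect_equal(schedule_value(cfg$sigma_schedule, t), 0.2)
    expect_equal(schedule_value(cfg$k_schedule, t), 5e5)
  }
  # annealing: at the stage temperature at t_train, peak 1 ps later,
  # cooled back by t_train + 15, held for the final 5
  expect_equal(schedule_value(cfg$temp_schedule, 50), 100)
  expect_equal(schedule_value(cfg$temp_schedule, 51), 300)
  expect_equal(schedule_value(cfg$temp_schedule, 65), 100)
  expect_equal(schedule_value(cfg$temp_schedule, 70), 100)
})

test_that("the temperature incarnations set stage-1 length and temperature", {
  cfg2 <- default_protocol(0.2, 3e5, variant = "150K/30")
  expect_equal(cfg2$stages[[1]]$t_to, 30)
  expect_equal(schedule_value(cfg2$temp_schedule, 10), 150)
  # hold scales with stage duration (3/50 of it)
  expect_equal(schedule_value(cfg2$sigma_schedule, 30 * 3 / 50), 0.6)
  cfg3 <- default_protocol(0.2, 3e5, variant = "200K/20")
  expect_equal(cfg3$stages[[1]]$t_to, 20)
  expect_equal(schedule_value(cfg3$temp_schedule, 10), 200)
})

test_that("schedules are monotone during training: sigma down, k up", {
  cfg <- default_protocol(0.13, 4.7e5, variant = "100K/50")
  tt <- seq(0, 50, by = 0.5)
  expect_true(all(diff(schedule_value(cfg$sigma_schedule, tt)) <= 1e-12))
  expect_true(all(diff(schedule_value(cfg$k_schedule, tt)) >= -1e-12))
})

test_that("a resolution decrease is rejected", {
  expect_error(default_protocol(0.7, 1e5), "sigma_stop")
  expect_error(default_protocol(0.2, -5), "k_stop")
})

fake_traj <- function(coord_list, times) {
  n <- nrow(coord_list[[1]])
  arr <- array(unlist(coord_list), dim = c(n, 3, length(coord_list)))
  structure(list(times = times, coords = arr, cc = rep(NA, length(times)),
                 vfit = 0, vff = 0, t_target = 0, stride = 1L, dt = 1),
            class = "trajectory")
}

test_that("final_model averages the trailing window", {
  fx <- std_fixture(n_atoms = 5)
  x <- fx$model$coords
  tr <- fake_traj(list(x, x, x), c(1, 2, 3))
  expect_equal(final_model(tr, 3, fx$model)$coords, x)
  y <- x + 0.4
  tr2 <- fake_traj(list(x, y), c(1, 2))
  expect_equal(final_model(tr2, 2, fx$model)$coords, (x + y) / 2)
  # only the window is used
  tr3 <- fake_traj(list(x + 99, x, y), c(1, 2, 3))
  expect_equal(final_model(tr3, 2, fx$model)$coords, (x + y) / 2)
  expect_error(final_model(tr3, 10, fx$model), "window")
})

test_that("averaging reduces positional spread below single-snapshot scatter", {
  fx <- std_fixture(n_atoms = 5)
  set.seed(42)
  snaps <- lapply(1:8, function(i)
    fx$model$coords + matrix(rnorm(15, sd = 0.05), 5, 3))
  tr <- fake_traj(snaps, 1:8)
  avg <- final_model(tr, 8, fx$model)$coords
  mean_dev_avg <- sqrt(mean(rowSums((avg - fx$model$coords)^2)))
  single_devs <- vapply(snaps, function(s)
    sqrt(mean(rowSums((s - fx$model$coords)^2))), numeric(1))
  expect_lt(mean_dev_avg, mean(single_devs))
})

test_that("k sweep rejects degenerate inputs", {
  fx <- std_fixture()
  cfg <- default_protocol(0.2, 1e5)
  expect_error(select_k_sweep(fx$model, fx$topo, fx$full, numeric(0), cfg),
               "empty")
  expect_warning(
    expect_error(select_k_sweep(fx$model, fx$topo, fx$full, c(1e5, 1e5),
                                cfg), "at least 2"),
    "duplicate")
})

test_that("on a noiseless self-map every k fits and the smallest adequate k wins", {
  # lower-resolution fixture (sigma_true 0.3 nm): smooth correlation
  # landscape, the regime where full-map-only sweeps are the published
  # fallback
  spec <- fixture_spec(n_atoms = 20, sigma_true = 0.3, seed = 7)
  px <- make_toy_polymer(spec)
  maps <- make_ground_truth_maps(px$model, spec)
  cfg <- default_protocol(0.3, 4e5, variant = "150K/30", seed = 5)
  res <- suppressWarnings(select_k_sweep(px$model, px$topo, maps$full,
                                         c(1e5, 2e5, 4e5), cfg))
  expect_true(all(res$table$stable))
  expect_true(all(res$table$cc > 0.99))
  expect_equal(res$best_k, 1e5)
  expect_s3_class(res$best_report, "refinement_report")
})

test_that("with the biasing potential off there is no systematic cc increase", {
  fx <- std_fixture()
  pm <- perturb_model(fx$model, 0.2, "thermal-like", seed = 99)
  slopes <- vapply(1:5, function(s) {
    cfg <- default_protocol(0.2, 1, variant = "200K/20", dt = 0.004,
                            seed = 100 + s)
    cfg$k_schedule <- parameter_schedule(cfg$k_schedule$times,
                                         rep(0, 4), "kJ/mol")
    cfg$k_stop <- 0
    rep_ <- suppressWarnings(run_refinement(pm, fx$topo, fx$half1, fx$half2,
                                            fx$full, cfg))
    cc <- c(rep_$stage1$cc, rep_$stage2$cc)
    tt <- c(rep_$stage1$times, rep_$stage2$times)
    unname(coef(lm(cc ~ tt))[2])
  }, numeric(1))
  ci <- t.test(slopes)$conf.int
  # the 95% interval must not lie entirely above zero
  expect_lte(ci[1], 0)
})

test_that("refining without a validation map warns and reports accordingly", {
  fx <- std_fixture()
  cfg <- default_protocol(0.2, 1e5, variant = "200K/20", dt = 0.004,
                          seed = 3)
  expect_warning(
    rep_ <- run_refinement(fx$model, fx$topo, fx$full, NULL, fx$full, cfg),
    "validation map")
  expect_equal(rep_$verdict, "no cross-validation")
  expect_true(all(vapply(rep_$crossval, function(r) is.null(r$val),
                         logical(1))))
})
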