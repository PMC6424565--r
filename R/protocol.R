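# The staged refinement protocol: a half-map training stage with sigma/k
# ramps and periodic FSC cross-validation, followed by a full-map stage with
# simulated annealing at constant sigma_stop/k_stop, and final-model
# averaging over the trailing window. Times are in toy picoseconds; the
# published ns-scale protocol maps onto them 1:1 in shape (1 ns -> 1 ps),
# preserving all schedule ratios.

#' Piecewise-linear parameter schedule
#'
#' @param times ascending node times (ps).
#' @param values node values; linear interpolation between nodes, clamped
#'   outside `[first, last]`.
#' @param units unit tag (`"nm"`, `"kJ/mol"` or `"K"`).
#' @return An object of class `parameter_schedule`.
#' @export
parameter_schedule <- function(times, values, units = "") {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values)) stop("times and values lengths differ")
  if (is.unsorted(times)) stop("times must be ascending")
  structure(list(times = times, values = values, units = units),
            class = "parameter_schedule")
}

#' Evaluate a schedule at given times
#' @param sched a [parameter_schedule].
#' @param t time(s) in ps.
#' @return Interpolated value(s), clamped outside the node range.
#' @export
schedule_value <- function(sched, t) {
  if (length(sched$times) == 1) return(rep(sched$values, length(t)))
  approx(sched$times, sched$values, xout = t, rule = 2)$y
}

#' Default continuous refinement protocol
#'
#' Builds the staged protocol: sigma and k are held at their start values
#' (0.6 nm, 0.5e5 kJ/mol) for the first 3/50 of the training stage, then
#' ramped linearly to `sigma_stop` / `k_stop` by the end of the stage.
#' Stage 1 refines against a training half-map at the variant temperature
#' (100 K for 50 ps, 150 K for 30 ps, or 200 K for 20 ps), cross-validating
#' every 5 ps. Stage 2 swaps in the full map for 15 ps of simulated
#' annealing (rapid heating to the peak temperature within `anneal_heat` ps,
#' then linear cooling back) plus 5 ps at the stage temperature, with sigma
#' and k held constant; k is never increased during the full-map stage.
#' The final model is the coordinate average over the trailing 5 ps.
#'
#' @param sigma_stop target Gaussian width, nm, in `(0, 0.6]`.
#' @param k_stop target force constant, kJ/mol (> 0).
#' @param variant temperature incarnation: `"100K/50"`, `"150K/30"` or
#'   `"200K/20"`.
#' @param anneal_peak annealing peak temperature, K (default 300; a 500 K /
#'   3 ps variant is available via `anneal_peak = 500, anneal_heat = 3`).
#' @param anneal_heat heating duration, ps (default 1).
#' @param crossval_stride cross-validation interval, ps (default 5).
#' @param crossval_threshold divergence flagging threshold (default 0.05).
#' @param crossval_smax frequency cap (1/Angstrom) for the divergence score,
#'   normally the map's nominal resolution; default `Inf` (all shells up to
#'   Nyquist).
#' @param sigma_start,k_start ramp start values (defaults 0.6 nm, 0.5e5).
#' @param dt integrator time step, ps.
#' @param friction Langevin friction, ps^-1.
#' @param seed integer seed.
#' @return An object of class `protocol_config`.
#' @export
default_protocol <- function(sigma_stop, k_stop,
                             variant = c("100K/50", "150K/30", "200K/20"),
                             anneal_peak = 300, anneal_heat = 1,
                             crossval_stride = 5, crossval_threshold = 0.05,
                             crossval_smax = Inf,
                             sigma_start = 0.6, k_start = 0.5e5,
                             dt = 0.002, friction = 5, seed = 1) {
  variant <- match.arg(variant)
  if (sigma_stop <= 0 || sigma_stop > sigma_start)
    stop("sigma_stop must be in (0, ", sigma_start,
         "]: resolution only increases during refinement")
  if (k_stop <= 0) stop("k_stop must be > 0")
  vt <- switch(variant, "100K/50" = c(100, 50), "150K/30" = c(150, 30),
               "200K/20" = c(200, 20))
  t_train <- vt[2]
  temp <- vt[1]
  hold <- 3 / 50 * t_train
  t_anneal <- 15
  t_final <- 5
  t_total <- t_train + t_anneal + t_final
  sigma_schedule <- parameter_schedule(
    c(0, hold, t_train, t_total), c(sigma_start, sigma_start, sigma_stop,
                                    sigma_stop), "nm")
  k_schedule <- parameter_schedule(
    c(0, hold, t_train, t_total), c(k_start, k_start, k_stop, k_stop),
    "kJ/mol")
  temp_schedule <- parameter_schedule(
    c(0, t_train, t_train + anneal_heat, t_train + t_anneal, t_total),
    c(temp, temp, anneal_peak, temp, temp), "K")
  structure(list(
    variant = variant,
    sigma_schedule = sigma_schedule, k_schedule = k_schedule,
    temp_schedule = temp_schedule,
    sigma_stop = sigma_stop, k_stop = k_stop,
    sigma_start = sigma_start, k_start = k_start,
    stages = list(
      list(name = "half-map training", map_role = "train",
           t_from = 0, t_to = t_train),
      list(name = "full-map annealing", map_role = "full",
           t_from = t_train, t_to = t_total)),
    anneal = list(peak = anneal_peak, heat = anneal_heat,
                  cool = t_anneal - anneal_heat),
    crossval_stride = crossval_stride,
    crossval_threshold = crossval_threshold,
    crossval_smax = crossval_smax,
    final_window = t_final, dt = dt, friction = friction,
    seed = as.integer(seed)),
    class = "protocol_config")
}

#' @export
print.protocol_config <- function(x, ...) {
  cat(sprintf("protocol_config (%s): sigma %.2f -> %.2f nm, k %.3g -> %.3g kJ/mol\n",
              x$variant, x$sigma_start, x$sigma_stop, x$k_start, x$k_stop))
  cat(sprintf("  stages: %s (0..%g ps), %s (..%g ps); anneal peak %g K; crossval every %g ps\n",
              x$stages[[1]]$name, x$stages[[1]]$t_to, x$stages[[2]]$name,
              x$stages[[2]]$t_to, x$anneal$peak, x$crossval_stride))
  invisible(x)
}

config_hash <- function(config) {
  # provenance fingerprint of the full configuration
  sub <- config[setdiff(names(config), character(0))]
  digestable <- paste(utils::capture.output(utils::str(sub, digits.d = 12)),
                      collapse = "\n")
  sum_ <- sum(utf8ToInt(digestable) * (seq_len(nchar(digestable)) %% 977))
  sprintf("%08x", sum_ %% .Machine$integer.max)
}

#' Coordinate-average final model from a trajectory window
#'
#' Unweighted per-atom mean over the snapshots in the trailing `window` ps.
#' No superposition is performed before averaging: the map frame anchors
#' the model.
#'
#' @param traj a `trajectory`.
#' @param window trailing duration (ps), `<=` trajectory span.
#' @param model the [atomic_model] carrying atom metadata.
#' @return The averaged [atomic_model].
#' @export
final_model <- function(traj, window, model) {
  t_end <- max(traj$times)
  if (window > t_end - min(traj$times) + traj$dt * traj$stride)
    stop("window exceeds trajectory span")
  sel <- which(traj$times > t_end - window + 1e-9)
  if (length(sel) == 0) sel <- length(traj$times)
  avg <- apply(traj$coords[, , sel, drop = FALSE], c(1, 2), mean)
  set_coords(model, avg)
}

#' Run the staged CDMD refinement
#'
#' Stage 1 integrates Langevin dynamics under the toy force field plus the
#' fitting potential against `train_map` with scheduled sigma(t), k(t),
#' logging cross-validation records every `crossval_stride` ps: the snapshot
#' model is stripped, spread at `sigma_stop`, and its FSC against the train
#' and validation maps compared (one-sided mean gap). If the final stage-1
#' record is flagged as overfitting, the report recommends (and stage 2
#' proceeds from) the latest earlier snapshot without a flag -- that is, a
#' structure at a lower force constant from the same trajectory. Stage 2
#' swaps in `full_map` and runs the annealing schedule with sigma and k
#' constant; the final model is the coordinate average over the trailing
#' window.
#'
#' @param model starting [atomic_model], pre-aligned to the map.
#' @param topo a [toy_topology].
#' @param train_map training [density_map] (half-map 1 or the full map).
#' @param val_map validation [density_map] (half-map 2), or NULL for
#'   full-map-only refinement (a warning is issued and no overfitting
#'   verdict is possible).
#' @param full_map full-reconstruction [density_map] for stage 2.
#' @param config a `protocol_config` from [default_protocol].
#' @param snapshot_stride snapshot interval in ps (default
#'   `crossval_stride / 10`).
#' @param weight_mode spreading weight mode.
#' @return An object of class `refinement_report`.
#' @export
run_refinement <- function(model, topo, train_map, val_map = NULL, full_map,
                           config, snapshot_stride = NULL,
                           weight_mode = "atomic_number") {
  stopifnot(inherits(config, "protocol_config"))
  assert_same_grid(train_map, full_map)
  if (!is.null(val_map)) assert_same_grid(train_map, val_map)
  else warning("no validation map: overfitting cannot be cross-validated (full-map-only refinement)")
  if (is.null(snapshot_stride)) snapshot_stride <- config$crossval_stride / 10
  dt <- config$dt
  stride_steps <- max(1L, round(snapshot_stride / dt))
  s1 <- config$stages[[1]]; s2 <- config$stages[[2]]

  providers1 <- list(
    toy_provider(topo),
    fit_provider(train_map, config$k_schedule, config$sigma_schedule, model,
                 weight_mode = weight_mode))
  th1 <- thermostat_schedule(config$temp_schedule$times,
                             config$temp_schedule$values,
                             friction = config$friction, seed = config$seed)
  n_steps1 <- round((s1$t_to - s1$t_from) / dt)
  traj1 <- integrate_langevin(model, providers1, th1, dt, n_steps1,
                              stride = stride_steps, t0 = s1$t_from,
                              topo = topo)

  # cross-validation records at the stride, FSC always computed at sigma_stop.
  # The divergence can be capped at the map's nominal resolution via
  # config$crossval_smax (1/Angstrom); by default every shell up to Nyquist
  # contributes.
  s_max <- config$crossval_smax
  if (is.null(s_max)) s_max <- Inf
  records <- list()
  cv_times <- seq(config$crossval_stride, s1$t_to, by = config$crossval_stride)
  for (tcv in cv_times) {
    i <- which.min(abs(traj1$times - tcv))
    snap <- set_coords(model, traj1$coords[, , i])
    sim <- model_to_map_for_fsc(snap, train_map, config$sigma_stop,
                                weight_mode)
    f_train <- compute_fsc(sim, train_map)
    rec <- list(time = traj1$times[i], train = f_train, val = NULL,
                divergence = 0, flagged = FALSE,
                k = schedule_value(config$k_schedule, traj1$times[i]))
    if (!is.null(val_map)) {
      f_val <- compute_fsc(sim, val_map)
      dv <- fsc_divergence(f_train, f_val, s_max = s_max,
                           threshold = config$crossval_threshold)
      rec$val <- f_val; rec$divergence <- dv$score; rec$flagged <- dv$flagged
    }
    records[[length(records) + 1]] <- rec
  }

  flagged_final <- length(records) > 0 &&
    records[[length(records)]]$flagged
  recommended <- NULL
  start2_coords <- traj1$final_coords
  if (flagged_final) {
    unflagged <- Filter(function(r) !r$flagged, records)
    if (length(unflagged) > 0) {
      best <- unflagged[[length(unflagged)]]  # largest earlier k without flag
    } else {
      # every record is flagged: fall back to the least-divergent snapshot
      divs <- vapply(records, `[[`, numeric(1), "divergence")
      best <- records[[which.min(divs)]]
    }
    i <- which.min(abs(traj1$times - best$time))
    start2_coords <- traj1$coords[, , i]
    recommended <- list(time = best$time, k = best$k,
                        divergence = best$divergence,
                        flagged = best$flagged)
  }

  # stage 2: full map, constant sigma_stop / k_stop, annealing thermostat
  providers2 <- list(
    toy_provider(topo),
    fit_provider(full_map, config$k_stop, config$sigma_stop, model,
                 weight_mode = weight_mode))
  th2 <- thermostat_schedule(config$temp_schedule$times,
                             config$temp_schedule$values,
                             friction = config$friction,
                             seed = config$seed + 1L)
  n_steps2 <- round((s2$t_to - s2$t_from) / dt)
  traj2 <- integrate_langevin(set_coords(model, start2_coords), providers2,
                              th2, dt, n_steps2, stride = stride_steps,
                              t0 = s2$t_from, topo = topo)

  fin <- final_model(traj2, config$final_window, model)
  final_fit <- fit_energy_forces(fin, full_map, config$k_stop,
                                 spread_params(config$sigma_stop, 4,
                                               weight_mode))
  verdict <- if (is.null(val_map)) "no cross-validation" else
    if (flagged_final) "overfitting" else "no overfitting"

  structure(list(
    stage1 = traj1, stage2 = traj2, crossval = records,
    final_model = fin, final_cc = final_fit$cc,
    sigma_stop = config$sigma_stop, k_stop = config$k_stop,
    verdict = verdict, recommended = recommended,
    energy_ratio = abs(final_fit$energy) /
      (abs(final_fit$energy) +
         abs(toy_energy_forces(fin, topo)$energy) + 1e-30),
    provenance = list(seed = config$seed, config_hash = config_hash(config),
                      variant = config$variant, dt = config$dt)),
    class = "refinement_report")
}

#' @export
print.refinement_report <- function(x, ...) {
  cat(sprintf("refinement_report: final cc = %.5f, sigma_stop = %.3g nm, k_stop = %.3g kJ/mol\n",
              x$final_cc, x$sigma_stop, x$k_stop))
  cat(sprintf("  overfitting verdict: %s", x$verdict))
  if (!is.null(x$recommended))
    cat(sprintf(" (recommended snapshot: t = %g ps, k = %.3g)",
                x$recommended$time, x$recommended$k))
  cat(sprintf("\n  provenance: seed %d, config %s\n", x$provenance$seed,
              x$provenance$config_hash))
  invisible(x)
}

#' Force-constant sweep for full-map-only refinement
#'
#' Runs one full-map-only refinement per force constant and tabulates the
#' final correlation, FSC_avg against the full map, and toy-geometry
#' diagnostics (RMS bond and angle deviations from equilibrium). Selects
#' the smallest k whose final correlation is within 1% of the best and
#' whose bond RMS deviation is below `geometry_bound`.
#'
#' @param model starting [atomic_model].
#' @param topo a [toy_topology].
#' @param full_map full [density_map].
#' @param k_values force constants to try (>= 2 after deduplication).
#' @param config a `protocol_config`; its `k_stop` is replaced per run.
#' @param geometry_bound maximum acceptable bond RMS deviation, nm
#'   (default 0.01).
#' @return List with `table` (one row per k), `best_k`, and `best_report`.
#' @export
select_k_sweep <- function(model, topo, full_map, k_values, config,
                           geometry_bound = 0.01) {
  k_values <- as.numeric(k_values)
  if (length(k_values) == 0) stop("empty k list")
  if (anyDuplicated(k_values)) {
    warning("duplicate k values removed")
    k_values <- unique(k_values)
  }
  if (length(k_values) < 2) stop("need at least 2 distinct k values")
  k_values <- sort(k_values)
  rows <- list(); reports <- list()
  for (k in k_values) {
    cfg <- config
    cfg$k_stop <- k
    k_start <- min(config$k_start, k)
    cfg$k_schedule <- parameter_schedule(
      config$k_schedule$times,
      ifelse(abs(config$k_schedule$values - config$k_start) < 1e-9,
             k_start, k), "kJ/mol")
    rep_k <- tryCatch(
      suppressWarnings(run_refinement(model, topo, full_map, NULL, full_map,
                                      cfg)),
      cdfit_instability = function(e) NULL)
    if (is.null(rep_k)) {
      rows[[length(rows) + 1]] <- data.frame(
        k = k, cc = NA, fsc_avg = NA, bond_rms = NA, angle_rms = NA,
        stable = FALSE)
      next
    }
    fin <- rep_k$final_model
    geo <- geometry_deviations(fin, topo)
    sim <- model_to_map_for_fsc(fin, full_map, cfg$sigma_stop)
    fc <- compute_fsc(sim, full_map)
    res <- resolution_at(fc)
    fa <- tryCatch(fsc_avg(fc, res$resolution), error = function(e) NA_real_)
    rows[[length(rows) + 1]] <- data.frame(
      k = k, cc = rep_k$final_cc, fsc_avg = fa, bond_rms = geo$bond_rms,
      angle_rms = geo$angle_rms, stable = TRUE)
    reports[[as.character(k)]] <- rep_k
  }
  tab <- do.call(rbind, rows)
  if (!any(tab$stable)) stop("all sweep runs were unstable")
  ok <- tab$stable
  best_cc <- max(tab$cc[ok])
  adequate <- ok & tab$cc >= best_cc * 0.99 & tab$bond_rms <= geometry_bound
  if (!any(adequate)) adequate <- ok & tab$cc >= best_cc * 0.99
  best_k <- min(tab$k[adequate])
  list(table = tab, best_k = best_k,
       best_report = reports[[as.character(best_k)]])
}

#' RMS deviations of bonds and angles from their equilibrium values
#' @param model an [atomic_model].
#' @param topo a [toy_topology].
#' @return List with `bond_rms` (nm) and `angle_rms` (rad).
#' @export
geometry_deviations <- function(model, topo) {
  x <- model$coords
  b <- topo$bonds
  dv <- x[b$j, , drop = FALSE] - x[b$i, , drop = FALSE]
  bond_rms <- sqrt(mean((sqrt(rowSums(dv^2)) - b$b0)^2))
  angle_rms <- NA_real_
  a <- topo$angles
  if (!is.null(a) && nrow(a) > 0) {
    rij <- x[a$i, , drop = FALSE] - x[a$j, , drop = FALSE]
    rkj <- x[a$k, , drop = FALSE] - x[a$j, , drop = FALSE]
    cth <- rowSums(rij * rkj) /
      (sqrt(rowSums(rij^2)) * sqrt(rowSums(rkj^2)))
    th <- acos(pmin(pmax(cth, -1), 1))
    angle_rms <- sqrt(mean((th - a$theta0)^2))
  }
  list(bond_rms = bond_rms, angle_rms = angle_rms)
}
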