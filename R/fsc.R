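# Fourier shell correlation between two maps, resolution estimation by the
# 0.143 criterion, FSC_avg integration, and the train/validation overfitting
# detector. Shells are taken by |q| in physical units (1/Angstrom), so
# anisotropic voxels are handled correctly; shell width is one frequency
# voxel of the largest axis.

#' Construct an FSC curve
#'
#' @param freqs shell-center spatial frequencies (1/Angstrom, ascending, > 0;
#'   the DC term is excluded).
#' @param values FSC per shell, real, in `[-1, 1]`.
#' @param shell_width frequency bin width (1/Angstrom).
#' @return An object of class `fsc_curve`.
#' @export
fsc_curve <- function(freqs, values, shell_width) {
  freqs <- as.numeric(freqs); values <- as.numeric(values)
  if (length(freqs) != length(values)) stop("freqs and values lengths differ")
  if (length(freqs) == 0) stop("empty FSC curve")
  if (any(freqs <= 0)) stop("shell frequencies must be > 0 (no DC term)")
  if (is.unsorted(freqs, strictly = TRUE)) stop("freqs must be ascending")
  if (any(abs(values) > 1 + 1e-9)) stop("|FSC| must be <= 1")
  structure(list(freqs = freqs, values = values,
                 shell_width = as.numeric(shell_width)),
            class = "fsc_curve")
}

#' @export
print.fsc_curve <- function(x, ...) {
  cat(sprintf("fsc_curve: %d shells, %.4g..%.4g 1/A (width %.4g)\n",
              length(x$freqs), min(x$freqs), max(x$freqs), x$shell_width))
  invisible(x)
}

# per-axis DFT frequencies in 1/Angstrom for n voxels of spacing d
fft_freqs <- function(n, d) {
  k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
  k / (n * d)
}

#' Fourier shell correlation between two maps
#'
#' `FSC(s) = Re sum_{q in shell s} F_a(q) conj(F_b(q)) /
#'  sqrt(sum |F_a|^2 sum |F_b|^2)`, with shells of width `1/(N*Delta)` where
#' `N` is the largest dim and `Delta` its voxel size. Shells run from the
#' first non-DC bin up to the smallest axis Nyquist frequency; empty shells
#' are skipped with a warning.
#'
#' @param a,b `density_map` objects on identical grids.
#' @return An [fsc_curve].
#' @export
compute_fsc <- function(a, b) {
  assert_same_grid(a, b)
  d <- dim(a$values)
  fa <- fft(a$values); fb <- fft(b$values)
  qx <- fft_freqs(d[1], a$voxel_size[1])
  qy <- fft_freqs(d[2], a$voxel_size[2])
  qz <- fft_freqs(d[3], a$voxel_size[3])
  q2 <- outer(outer(qx^2, qy^2, `+`), qz^2, `+`)
  qabs <- sqrt(q2)
  big <- which.max(d)
  w <- 1 / (d[big] * a$voxel_size[big])
  nyq <- min(1 / (2 * a$voxel_size))
  shell <- as.integer(round(qabs / w))
  nmax <- floor(nyq / w + 1e-9)
  cross <- fa * Conj(fb)
  pa <- Re(fa * Conj(fa)); pb <- Re(fb * Conj(fb))
  keep <- shell >= 1L & shell <= nmax
  s <- shell[keep]
  num <- vapply(split(Re(cross)[keep], s), sum, numeric(1))
  da <- vapply(split(pa[keep], s), sum, numeric(1))
  db <- vapply(split(pb[keep], s), sum, numeric(1))
  bins <- as.integer(names(num))
  expected <- seq_len(nmax)
  if (!all(expected %in% bins))
    warning("skipping empty FSC shells: ",
            paste(setdiff(expected, bins), collapse = ","))
  ok <- da > 0 & db > 0
  if (!all(ok)) {
    warning("skipping FSC shells with zero power: ",
            paste(bins[!ok], collapse = ","))
    num <- num[ok]; da <- da[ok]; db <- db[ok]; bins <- bins[ok]
  }
  vals <- num / sqrt(da * db)
  vals <- pmin(pmax(vals, -1), 1)
  fsc_curve(bins * w, vals, w)
}

#' Nominal resolution from an FSC curve
#'
#' Finds the first downward crossing of `threshold`, linearly interpolated
#' between adjacent shells, and returns `r = 1/s*` in Angstrom. If the curve
#' starts below the threshold the first shell is reported with
#' `boundary = TRUE`; if the curve never drops below the threshold the
#' smallest-axis Nyquist resolution is returned with `no_crossing = TRUE`.
#'
#' @param curve an [fsc_curve].
#' @param threshold FSC threshold in `(-1, 1)` (default 0.143).
#' @return A list with `resolution` (Angstrom), `freq` (1/Angstrom),
#'   `no_crossing` and `boundary` flags.
#' @export
resolution_at <- function(curve, threshold = 0.143) {
  stopifnot(inherits(curve, "fsc_curve"))
  if (threshold <= -1 || threshold >= 1)
    stop("threshold must be inside (-1, 1)")
  f <- curve$freqs; v <- curve$values
  if (v[1] < threshold)
    return(list(resolution = 1 / f[1], freq = f[1], no_crossing = FALSE,
                boundary = TRUE))
  idx <- which(v[-1] < threshold & v[-length(v)] >= threshold)
  if (length(idx) == 0) {
    nyq <- f[length(f)] + curve$shell_width / 2
    return(list(resolution = 1 / nyq, freq = nyq, no_crossing = TRUE,
                boundary = FALSE))
  }
  i <- idx[1]
  s_star <- f[i] + (f[i + 1] - f[i]) * (v[i] - threshold) / (v[i] - v[i + 1])
  list(resolution = 1 / s_star, freq = s_star, no_crossing = FALSE,
       boundary = FALSE)
}

#' Average FSC over the resolution range
#'
#' Trapezoidal integral of the FSC over spatial frequencies from
#' `1/100 A^-1` to `1/r`, divided by the interval length, so a constant
#' curve returns its constant. The curve is linearly interpolated between
#' shells and clamped to its end values outside its support.
#'
#' @param curve an [fsc_curve].
#' @param r resolution in Angstrom; must satisfy `1/r > 1/100`.
#' @return The average FSC (dimensionless).
#' @export
fsc_avg <- function(curve, r) {
  stopifnot(inherits(curve, "fsc_curve"))
  s_lo <- 1 / 100
  s_hi <- 1 / r
  if (!is.finite(s_hi) || s_hi <= s_lo)
    stop("invalid resolution r = ", r, " A: need 1/r > 1/100 A^-1")
  nodes <- sort(unique(c(s_lo, s_hi,
                         curve$freqs[curve$freqs > s_lo &
                                       curve$freqs < s_hi])))
  y <- approx(curve$freqs, curve$values, xout = nodes, rule = 2)$y
  integral <- sum(diff(nodes) * (head(y, -1) + tail(y, -1)) / 2)
  integral / (s_hi - s_lo)
}

#' Train/validation FSC divergence (overfitting detector)
#'
#' One-sided mean gap `mean(max(0, FSC_train - FSC_val))` over shells with
#' frequency `<= s_max`; flagged when the score exceeds `threshold`.
#' One-sided because overfitting inflates the training-map FSC specifically.
#'
#' @param train,val [fsc_curve]s sharing identical shell frequencies.
#' @param s_max frequency cap in 1/Angstrom (default: all shells).
#' @param threshold flagging threshold (default 0.05).
#' @return A list with `score` (>= 0) and `flagged`.
#' @export
fsc_divergence <- function(train, val, s_max = Inf, threshold = 0.05) {
  stopifnot(inherits(train, "fsc_curve"), inherits(val, "fsc_curve"))
  if (length(train$freqs) != length(val$freqs) ||
      any(abs(train$freqs - val$freqs) > 1e-9))
    stop("train and val curves must share shell frequencies")
  keep <- train$freqs <= s_max
  if (!any(keep)) stop("no shells at or below s_max = ", s_max)
  score <- mean(pmax(0, train$values[keep] - val$values[keep]))
  list(score = score, flagged = score > threshold)
}

#' Simulated density of a stripped model for FSC evaluation
#'
#' Drops waters, ions and hydrogens from the model and spreads the remaining
#' atoms at `sigma_stop` on the template grid, as done when comparing
#' refinement snapshots against half-maps.
#'
#' @param model an [atomic_model].
#' @param template a [density_map] providing the grid.
#' @param sigma_stop Gaussian width in nm.
#' @param weight_mode passed to [spread_params].
#' @return A [density_map].
#' @export
model_to_map_for_fsc <- function(model, template, sigma_stop,
                                 weight_mode = "atomic_number") {
  stripped <- strip_model(model)
  stripped$fit_mask[] <- TRUE  # FSC uses all retained atoms
  spread_atoms(stripped, template, spread_params(sigma_stop, 4, weight_mode))
}
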