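#' @useDynLib cdfit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx rnorm runif sd setNames
#' @importFrom utils read.csv write.csv head tail
NULL

#' Length-unit conversion at the map boundary
#'
#' Model coordinates and Gaussian widths are stored in nm; density-map grids
#' use Angstrom (the file convention). This factor is applied in exactly one
#' place per conversion.
#' @export
ANGSTROM_PER_NM <- 10

#' Construct a density map
#'
#' A `density_map` is a 3D scalar field on a regular orthorhombic grid. The
#' physical position of voxel `(i, j, k)` (zero-based) is
#' `origin + c(i, j, k) * voxel_size`, with `origin` referring to the *center*
#' of voxel `(0, 0, 0)`. Lengths are in Angstrom. Values may be negative
#' (hydrophobic regions in experimental maps by convention) and are never
#' clipped.
#'
#' @param values 3D numeric array of densities (arbitrary units, finite).
#' @param voxel_size grid spacing per axis in Angstrom; scalar or length-3.
#' @param origin physical coordinate (Angstrom) of the center of voxel
#'   `(0, 0, 0)`; length-3.
#' @param label free-text role tag, e.g. `"experimental"`, `"simulated"`,
#'   `"half1"`, `"half2"`, `"full"`.
#' @return An object of class `density_map`.
#' @export
density_map <- function(values, voxel_size, origin = c(0, 0, 0),
                        label = "map") {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("values must be a 3D array")
  if (any(dim(values) < 2L)) stop("all dims must be >= 2")
  if (!all(is.finite(values))) stop("all map values must be finite")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(voxel_size <= 0)) stop("voxel_size components must be > 0")
  origin <- rep_len(as.numeric(origin), 3L)
  if (!all(is.finite(origin))) stop("origin must be finite")
  structure(list(values = values, voxel_size = voxel_size, origin = origin,
                 label = as.character(label)[1]),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("density_map '%s': %d x %d x %d voxels\n", x$label,
              d[1], d[2], d[3]))
  cat(sprintf("  voxel size (A): %.4f %.4f %.4f\n", x$voxel_size[1],
              x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  origin (A):     %.3f %.3f %.3f\n", x$origin[1],
              x$origin[2], x$origin[3]))
  cat(sprintf("  value range:    [%.4g, %.4g], mean %.4g\n",
              min(x$values), max(x$values), mean(x$values)))
  invisible(x)
}

#' Map dimensions
#' @param map a `density_map`.
#' @return integer vector of voxel counts per axis.
#' @export
map_dims <- function(map) dim(map$values)

#' Check that two maps share a grid
#'
#' @param a,b `density_map` objects.
#' @param tol absolute tolerance (Angstrom) for spacing and origin.
#' @return TRUE invisibly, or an error naming both grids.
#' @export
assert_same_grid <- function(a, b, tol = 1e-4) {
  ok <- identical(dim(a$values), dim(b$values)) &&
    all(abs(a$voxel_size - b$voxel_size) <= tol) &&
    all(abs(a$origin - b$origin) <= tol)
  if (!ok)
    stop(sprintf(
      "grid mismatch: '%s' is %s / vox %s / origin %s but '%s' is %s / vox %s / origin %s",
      a$label, paste(dim(a$values), collapse = "x"),
      paste(signif(a$voxel_size, 6), collapse = ","),
      paste(signif(a$origin, 6), collapse = ","),
      b$label, paste(dim(b$values), collapse = "x"),
      paste(signif(b$voxel_size, 6), collapse = ","),
      paste(signif(b$origin, 6), collapse = ",")))
  invisible(TRUE)
}

#' Read an MRC/CCP4 density map
#'
#' Parses an MRC2014 / CCP4 volume (mode 2, 32-bit float). The axis
#' permutation header fields (`MAPC`, `MAPR`, `MAPS`) are honoured and the
#' grid is canonicalized so that the fastest-varying memory axis is x.
#' The origin is taken from the MRC2000 `ORIGIN` record if set, otherwise
#' from `NXSTART`/`NYSTART`/`NZSTART` times the voxel size. Negative voxel
#' values are preserved.
#'
#' @param path path to an MRC/CCP4 file.
#' @param label role tag for the returned map (default: file name).
#' @return A [density_map].
#' @export
read_map <- function(path, label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_i <- readBin(con, "integer", n = 256L, size = 4L, endian = "little")
  seek(con, 0)
  hdr_f <- readBin(con, "numeric", n = 256L, size = 4L, endian = "little")
  nfile <- hdr_i[1:3]                      # counts along column/row/section
  mode <- hdr_i[4]
  if (any(!is.finite(nfile)) || any(nfile < 1L) || any(nfile > 100000L))
    stop("malformed header: implausible NX/NY/NZ = ",
         paste(nfile, collapse = ","))
  if (mode != 2L)
    stop("unsupported MODE = ", mode, " (only mode 2, 32-bit float volumes)")
  nstart <- hdr_i[5:7]
  m_grid <- hdr_i[8:10]
  cella <- hdr_f[11:13]
  axis_map <- hdr_i[17:19]                 # MAPC, MAPR, MAPS
  if (!identical(sort(axis_map), 1:3))
    stop("malformed header: MAPC/MAPR/MAPS = ",
         paste(axis_map, collapse = ","), " is not a permutation of 1:3")
  if (any(m_grid < 1L)) stop("malformed header: MX/MY/MZ = ",
                             paste(m_grid, collapse = ","))
  if (any(!is.finite(cella)) || any(cella <= 0))
    stop("malformed header: CELLA = ", paste(cella, collapse = ","))
  origin_rec <- hdr_f[50:52]
  nsymbt <- hdr_i[24]
  seek(con, 1024 + max(0L, nsymbt))
  nvox <- prod(nfile)
  vals <- readBin(con, "numeric", n = nvox, size = 4L, endian = "little")
  if (length(vals) < nvox) stop("malformed file: truncated voxel data")
  if (any(is.nan(vals))) stop("map contains NaN voxels")
  raw <- array(vals, dim = nfile)
  # canonicalize: file axis d holds crystal axis axis_map[d]
  values <- aperm(raw, order(axis_map))
  voxel <- cella / m_grid                  # CELLA and MX/MY/MZ are canonical
  if (any(abs(origin_rec) > 1e-6) && all(is.finite(origin_rec))) {
    origin <- origin_rec
  } else {
    # NXSTART is in file axis order; reorder to canonical
    origin <- nstart[order(axis_map)] * voxel
  }
  density_map(values, voxel, origin,
              label = if (is.null(label)) basename(path) else label)
}

#' Write an MRC/CCP4 density map
#'
#' Writes a standard MRC2014 volume (mode 2, 32-bit float) in canonical
#' axis order (`MAPC`,`MAPR`,`MAPS` = 1,2,3) with the voxel size recorded in
#' `CELLA`/`MX..MZ` and the origin in the MRC2000 `ORIGIN` record.
#'
#' @param map a [density_map].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop("cannot open for writing: ", path))
  on.exit(close(con))
  d <- dim(map$values)
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  v <- as.numeric(map$values)
  wi(d)                       # NX NY NZ
  wi(2L)                      # MODE 2: float32
  wi(c(0L, 0L, 0L))           # NXSTART..
  wi(d)                       # MX MY MZ
  wf(d * map$voxel_size)      # CELLA
  wf(c(90, 90, 90))           # CELLB
  wi(1:3)                     # MAPC MAPR MAPS (canonical)
  wf(c(min(v), max(v), mean(v)))  # DMIN DMAX DMEAN
  wi(c(1L, 0L))               # ISPG, NSYMBT
  wi(integer(25))             # EXTRA (words 26..49, word 50 starts ORIGIN)
  wf(map$origin)              # ORIGIN (MRC2000)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(sd(v) * sqrt((length(v) - 1) / length(v)))     # RMS about mean
  wi(0L)                      # NLABL
  writeBin(raw(800L), con)    # labels
  writeBin(v, con, size = 4L, endian = "little")
  invisible(path)
}

#' Trim a map to an orthorhombic sub-box
#'
#' Retains voxels with zero-based indices `lo <= idx < hi` per axis and
#' shifts the origin so that the physical coordinates of retained voxels are
#' unchanged.
#'
#' @param map a [density_map].
#' @param lo,hi integer voxel index triples, zero-based half-open box
#'   (`0 <= lo < hi <= dims`).
#' @return Trimmed [density_map].
#' @export
trim_map <- function(map, lo, hi) {
  stopifnot(inherits(map, "density_map"))
  lo <- as.integer(rep_len(lo, 3L)); hi <- as.integer(rep_len(hi, 3L))
  d <- dim(map$values)
  if (any(lo < 0L) || any(hi > d) || any(lo >= hi))
    stop("invalid trim box: need 0 <= lo < hi <= dims, got lo=",
         paste(lo, collapse = ","), " hi=", paste(hi, collapse = ","),
         " dims=", paste(d, collapse = ","))
  if (any(hi - lo < 2L)) stop("trim box must keep >= 2 voxels per axis")
  vals <- map$values[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2],
                     (lo[3] + 1):hi[3], drop = FALSE]
  density_map(vals, map$voxel_size, map$origin + lo * map$voxel_size,
              label = map$label)
}

#' Resample a map onto a new grid by trilinear interpolation
#'
#' The new grid spans the same physical box as the old one (box edges taken
#' half a voxel beyond the first/last voxel centers), so the total physical
#' extent is preserved. Values at new voxel centers are obtained by trilinear
#' interpolation with clamping at the box faces.
#'
#' @param map a [density_map].
#' @param new_dims target voxel counts per axis (each >= 2).
#' @return Resampled [density_map].
#' @export
resample_map <- function(map, new_dims) {
  stopifnot(inherits(map, "density_map"))
  new_dims <- as.integer(rep_len(new_dims, 3L))
  if (any(new_dims < 2L)) stop("new_dims must be >= 2 per axis")
  d <- dim(map$values)
  if (identical(new_dims, d)) return(map)
  new_vox <- d * map$voxel_size / new_dims
  new_origin <- map$origin - map$voxel_size / 2 + new_vox / 2
  # fractional old-grid coordinates of new voxel centers, per axis
  ax <- lapply(1:3, function(a) {
    g <- (new_origin[a] + (0:(new_dims[a] - 1)) * new_vox[a] -
            map$origin[a]) / map$voxel_size[a]
    pmin(pmax(g, 0), d[a] - 1)
  })
  f <- lapply(seq_along(ax), function(a)
    pmin(floor(ax[[a]]), d[a] - 2))        # lower corner, keeps +1 in range
  t_ <- lapply(seq_along(ax), function(a) ax[[a]] - f[[a]])
  i0 <- f[[1]] + 1L; j0 <- f[[2]] + 1L; k0 <- f[[3]] + 1L
  tx <- t_[[1]]; ty <- t_[[2]]; tz <- t_[[3]]
  out <- array(0, dim = new_dims)
  V <- map$values
  # vectorized over x for each (j,k) column pair
  for (kk in seq_len(new_dims[3])) {
    k <- k0[kk]; wz <- tz[kk]
    for (jj in seq_len(new_dims[2])) {
      j <- j0[jj]; wy <- ty[jj]
      c00 <- V[i0, j, k] * (1 - tx) + V[i0 + 1L, j, k] * tx
      c10 <- V[i0, j + 1L, k] * (1 - tx) + V[i0 + 1L, j + 1L, k] * tx
      c01 <- V[i0, j, k + 1L] * (1 - tx) + V[i0 + 1L, j, k + 1L] * tx
      c11 <- V[i0, j + 1L, k + 1L] * (1 - tx) + V[i0 + 1L, j + 1L, k + 1L] * tx
      out[, jj, kk] <- (c00 * (1 - wy) + c10 * wy) * (1 - wz) +
        (c01 * (1 - wy) + c11 * wy) * wz
    }
  }
  density_map(out, new_vox, new_origin, label = map$label)
}

#' Value of a map at a physical coordinate (nearest voxel)
#'
#' @param map a [density_map].
#' @param xyz physical coordinate (Angstrom), length-3.
#' @return The value of the voxel whose center is nearest to `xyz`.
#' @export
map_value_at <- function(map, xyz) {
  idx <- round((as.numeric(xyz) - map$origin) / map$voxel_size)
  d <- dim(map$values)
  if (any(idx < 0) || any(idx >= d)) stop("coordinate outside map")
  map$values[idx[1] + 1L, idx[2] + 1L, idx[3] + 1L]
}
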