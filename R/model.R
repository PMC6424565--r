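# Atomic models: particle coordinates in nm plus spreading weights, the
# fit mask (which atoms feel the biasing potential), masses and residue/chain
# metadata. PDB input/output is delegated to bio3d.

ATOMIC_NUMBER <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16,
                   MG = 12, K = 19, "NA" = 11, CL = 17, CA = 20, ZN = 30,
                   FE = 26)

WATER_RESNAMES <- c("HOH", "WAT", "TIP3", "TIP3P", "SOL", "SPC", "H2O")
ION_RESNAMES <- c("NA", "CL", "K", "MG", "CA", "ZN", "MN", "FE", "CU",
                  "NA+", "CL-", "K+", "MG2", "SOD", "CLA", "POT")

#' Construct an atomic model
#'
#' @param coords n x 3 numeric matrix of atom positions in nm.
#' @param weights per-atom spreading amplitudes (>= 0); recycled.
#' @param fit_mask per-atom logical, `TRUE` for atoms that feel the density
#'   fitting potential; recycled.
#' @param masses per-atom masses in amu; recycled (default 12).
#' @param element per-atom element symbols; recycled.
#' @param resno per-atom residue index; recycled.
#' @param resid per-atom residue name; recycled.
#' @param chain per-atom chain identifier; recycled.
#' @return An object of class `atomic_model`.
#' @export
atomic_model <- function(coords, weights = 1, fit_mask = TRUE, masses = 12,
                         element = "C", resno = NULL, resid = "ALA",
                         chain = "A") {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an n x 3 matrix")
  if (!all(is.finite(coords))) stop("coords must be finite")
  n <- nrow(coords)
  weights <- rep_len(as.numeric(weights), n)
  if (any(weights < 0)) stop("weights must be >= 0")
  fit_mask <- rep_len(as.logical(fit_mask), n)
  masses <- rep_len(as.numeric(masses), n)
  if (any(masses <= 0)) stop("masses must be > 0")
  if (is.null(resno)) resno <- seq_len(n)
  structure(list(coords = coords, weights = weights, fit_mask = fit_mask,
                 masses = masses, element = rep_len(element, n),
                 resno = rep_len(as.integer(resno), n),
                 resid = rep_len(resid, n), chain = rep_len(chain, n)),
            class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  cat(sprintf("atomic_model: %d atoms (%d in fit mask), %d residues\n",
              nrow(x$coords), sum(x$fit_mask), length(unique(x$resno))))
  invisible(x)
}

#' Number of atoms in a model
#' @param model an `atomic_model`.
#' @return integer atom count.
#' @export
n_atoms <- function(model) nrow(model$coords)

#' Replace model coordinates
#' @param model an `atomic_model`.
#' @param coords n x 3 matrix in nm.
#' @return The model with new coordinates.
#' @export
set_coords <- function(model, coords) {
  coords <- as.matrix(coords)
  stopifnot(identical(dim(coords), dim(model$coords)))
  model$coords <- coords
  model
}

#' Read an atomic model from a PDB file
#'
#' Coordinates are converted from the PDB Angstrom convention to nm.
#'
#' @param path PDB file path.
#' @return An [atomic_model] with all atoms in the fit mask.
#' @export
read_model <- function(path) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  elem <- toupper(trimws(at$elesy))
  elem[is.na(elem) | elem == ""] <-
    substr(trimws(at$elety[is.na(elem) | elem == ""]), 1, 1)
  atomic_model(cbind(at$x, at$y, at$z) / ANGSTROM_PER_NM,
               weights = 1, fit_mask = TRUE,
               masses = ifelse(elem %in% names(ATOMIC_NUMBER),
                               pmax(ATOMIC_NUMBER[elem], 1) * 2, 12),
               element = elem, resno = at$resno, resid = at$resid,
               chain = ifelse(is.na(at$chain), "A", at$chain))
}

#' Write an atomic model to a PDB file
#'
#' @param model an [atomic_model].
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  xyz <- as.vector(t(model$coords * ANGSTROM_PER_NM))
  bio3d::write.pdb(file = path, xyz = xyz, resno = model$resno,
                   resid = model$resid, chain = model$chain,
                   elety = rep_len(ifelse(model$element == "", "C",
                                          model$element), n_atoms(model)),
                   elesy = model$element)
  invisible(path)
}

#' Strip solvent, ions and hydrogens from a model
#'
#' Removes water and ion residues, hydrogen atoms, and atoms excluded from
#' the fit mask when `mask_only = TRUE`. Used before converting snapshots to
#' simulated densities for FSC evaluation.
#'
#' @param model an [atomic_model].
#' @param mask_only also drop atoms outside the fit mask (default FALSE).
#' @return The stripped [atomic_model].
#' @export
strip_model <- function(model, mask_only = FALSE) {
  resid <- toupper(trimws(model$resid))
  elem <- toupper(trimws(model$element))
  keep <- !(resid %in% WATER_RESNAMES) & !(resid %in% ION_RESNAMES) &
    elem != "H"
  if (mask_only) keep <- keep & model$fit_mask
  if (!any(keep)) stop("no atoms left after stripping waters/ions/hydrogens")
  subset_model(model, keep)
}

#' Subset a model by atom
#' @param model an [atomic_model].
#' @param keep logical or integer atom selection.
#' @return The selected [atomic_model].
#' @export
subset_model <- function(model, keep) {
  atomic_model(model$coords[keep, , drop = FALSE], model$weights[keep],
               model$fit_mask[keep], model$masses[keep], model$element[keep],
               model$resno[keep], model$resid[keep], model$chain[keep])
}

#' Spreading amplitudes under a weighting mode
#'
#' `"uniform"` gives every atom amplitude `weights`; `"atomic_number"`
#' multiplies by the element's atomic number (unknown elements count as
#' carbon), reflecting that heavier atoms scatter more.
#'
#' @param model an [atomic_model].
#' @param weight_mode `"uniform"` or `"atomic_number"`.
#' @return Numeric per-atom amplitude vector.
#' @export
effective_weights <- function(model, weight_mode = c("atomic_number",
                                                     "uniform")) {
  weight_mode <- match.arg(weight_mode)
  w <- model$weights
  if (weight_mode == "atomic_number") {
    z <- ATOMIC_NUMBER[toupper(model$element)]
    z[is.na(z)] <- 6
    w <- w * as.numeric(z)
  }
  w
}
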