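# Validation statistics: per-residue outlier propensity and least-squares
# superposition RMSD. Outlier detection itself (rotamer / Ramachandran
# evaluation) is external; this module consumes outlier count tables and
# computes the propensity statistic.

#' Per-residue-type outlier propensity
#'
#' For each amino-acid type, the probability that a residue of that type is
#' an outlier is `P(out | aa) = n_aa / N_aa`. The Bayes factorization terms
#' are returned for reporting: `P(aa | out) = n_aa / n_tot`,
#' `P(out) = n_tot / N_tot`, `P(aa) = N_aa / N_tot`; the composition
#' `P(aa | out) P(out) / P(aa)` equals `n_aa / N_aa` identically.
#' Types with `N_aa = 0` are omitted with a warning (undefined propensity).
#'
#' @param counts data frame with columns `residue_type`, `N_aa` (total count
#'   in the sequence) and `n_aa` (outlier count), `0 <= n_aa <= N_aa`.
#' @return Data frame with columns `residue_type`, `N_aa`, `n_aa`,
#'   `propensity`, `p_aa_given_out`, `p_out`, `p_aa`.
#' @export
outlier_propensity <- function(counts) {
  counts <- as.data.frame(counts)
  stopifnot(all(c("residue_type", "N_aa", "n_aa") %in% names(counts)))
  if (any(counts$n_aa < 0) || any(counts$N_aa < 0))
    stop("counts must be >= 0")
  if (any(counts$n_aa > counts$N_aa))
    stop("n_aa > N_aa for type(s): ",
         paste(counts$residue_type[counts$n_aa > counts$N_aa],
               collapse = ", "))
  if (any(counts$N_aa == 0)) {
    warning("omitting types with N_aa = 0 (undefined propensity): ",
            paste(counts$residue_type[counts$N_aa == 0], collapse = ", "))
    counts <- counts[counts$N_aa > 0, , drop = FALSE]
  }
  n_tot <- sum(counts$n_aa)
  N_tot <- sum(counts$N_aa)
  data.frame(
    residue_type = counts$residue_type,
    N_aa = counts$N_aa, n_aa = counts$n_aa,
    propensity = counts$n_aa / counts$N_aa,
    p_aa_given_out = if (n_tot > 0) counts$n_aa / n_tot else NA_real_,
    p_out = n_tot / N_tot,
    p_aa = counts$N_aa / N_tot)
}

#' Merge outlier count tables
#'
#' Concatenates counts across structures (e.g. pre-equilibration and
#' post-refinement snapshots) by summing `N_aa` and `n_aa` per type.
#'
#' @param ... data frames with `residue_type`, `N_aa`, `n_aa` columns.
#' @return The merged count data frame.
#' @export
merge_outlier_counts <- function(...) {
  all_ <- do.call(rbind, lapply(list(...), as.data.frame))
  agg <- stats::aggregate(cbind(N_aa, n_aa) ~ residue_type, data = all_,
                          FUN = sum)
  agg[order(agg$residue_type), , drop = FALSE]
}

#' Kabsch superposition and RMSD
#'
#' With `align = TRUE`, computes the optimal proper least-squares rotation
#' and translation of `mobile` onto `reference` over the alignment
#' selection, then reports the RMSD over the (possibly different) scoring
#' selection. With `align = FALSE`, the raw coordinate RMSD is reported.
#'
#' @param mobile,reference [atomic_model]s (or n x 3 matrices, nm) with
#'   atoms in 1:1 correspondence.
#' @param selection atom indices (or logical) used for the alignment fit
#'   (default: all atoms; at least 3 for alignment).
#' @param score_selection atom indices used for the RMSD (default:
#'   `selection`).
#' @param align perform the least-squares fit first (default TRUE).
#' @return List of class `superposition` with `rotation` (3 x 3, det +1),
#'   `translation` (nm), `rmsd` (nm), `unit`, and the selections used.
#' @export
superpose_rmsd <- function(mobile, reference, selection = NULL,
                           score_selection = NULL, align = TRUE) {
  xm <- if (inherits(mobile, "atomic_model")) mobile$coords else
    as.matrix(mobile)
  xr <- if (inherits(reference, "atomic_model")) reference$coords else
    as.matrix(reference)
  if (!identical(dim(xm), dim(xr)))
    stop("selection mismatch: models have different atom counts (",
         nrow(xm), " vs ", nrow(xr), ")")
  n <- nrow(xm)
  if (is.null(selection)) selection <- seq_len(n)
  if (is.logical(selection)) selection <- which(selection)
  if (is.null(score_selection)) score_selection <- selection
  if (is.logical(score_selection)) score_selection <- which(score_selection)
  if (any(selection < 1 | selection > n) ||
      any(score_selection < 1 | score_selection > n))
    stop("selection index out of range")
  rotation <- diag(3)
  translation <- c(0, 0, 0)
  fitted <- xm
  if (align) {
    if (length(selection) < 3)
      stop("need >= 3 atoms for alignment, got ", length(selection))
    a <- xm[selection, , drop = FALSE]
    b <- xr[selection, , drop = FALSE]
    ca <- colMeans(a); cb <- colMeans(b)
    H <- t(sweep(a, 2, ca)) %*% sweep(b, 2, cb)
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    D <- diag(c(1, 1, d))
    rotation <- sv$v %*% D %*% t(sv$u)       # maps mobile -> reference frame
    translation <- cb - as.numeric(rotation %*% ca)
    fitted <- sweep(xm %*% t(rotation), 2, translation, `+`)
  }
  dsel <- fitted[score_selection, , drop = FALSE] -
    xr[score_selection, , drop = FALSE]
  rmsd <- sqrt(mean(rowSums(dsel^2)))
  structure(list(rotation = rotation, translation = translation,
                 rmsd = rmsd, unit = "nm", selection = selection,
                 score_selection = score_selection, align = align),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: rmsd = %.4f %s over %d atoms (%s)\n",
              x$rmsd, x$unit, length(x$score_selection),
              if (x$align) sprintf("aligned on %d atoms",
                                   length(x$selection)) else "no alignment"))
  invisible(x)
}

#' Plain coordinate RMSD between two models (nm)
#' @param a,b [atomic_model]s or n x 3 matrices with matched atoms.
#' @return RMSD in nm without superposition.
#' @export
rmsd_nm <- function(a, b) superpose_rmsd(a, b, align = FALSE)$rmsd
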