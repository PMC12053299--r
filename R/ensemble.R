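## Multi-conformer-single-tensor (MCST) fitting: conformers are
## superposed into a common Eckart frame (mass-weighted RMSD-minimizing
## proper rotation, Kabsch) and one tensor is fitted to
## population-weighted RDC predictions.

## Mass-weighted Kabsch rotation: proper rotation R minimizing
## sum m_i |R(b_i - cb) - (a_i - ca)|^2.
.kabsch <- function(ref, mov, mass) {
  ca <- colSums(ref * mass) / sum(mass)
  cb <- colSums(mov * mass) / sum(mass)
  A <- sweep(ref, 2, ca); B <- sweep(mov, 2, cb)
  C <- t(B * mass) %*% A
  sv <- svd(C)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, centerRef = ca, centerMov = cb)
}

#' Superpose a conformer into the Eckart frame of a reference
#'
#' Translates \code{conf} to its mass-weighted centroid and applies the
#' proper rotation minimizing the mass-weighted RMSD to \code{ref},
#' which satisfies the rotational Eckart condition for similar
#' structures. Internal geometry is preserved exactly (rigid-body
#' transform).
#'
#' @param ref reference \linkS4class{Conformer}.
#' @param conf conformer to superpose; must share the atom labels of the
#'   superposition subset with \code{ref}.
#' @param subset optional character vector of atom labels used to define
#'   the frame; default NULL uses all shared heavy (non-hydrogen) atoms.
#'   The transform is always applied to all atoms.
#' @return the transformed \linkS4class{Conformer}.
#' @export
eckartSuperpose <- function(ref, conf, subset = NULL) {
  ra <- atoms(ref); ca <- atoms(conf)
  if (is.null(subset)) {
    subset <- intersect(ra$label[ra$element != "H"],
                        ca$label[ca$element != "H"])
    if (length(subset) == 0)
      subset <- intersect(ra$label, ca$label)
    if (length(subset) == 0)
      .err("rdcLabelError", "conformers share no atom labels")
  }
  if (length(subset) == 0 ||
      !all(subset %in% ra$label) || !all(subset %in% ca$label))
    .err("rdcLabelError", "superposition subset not shared by both conformers")
  if (length(subset) < 3)
    .err("rdcGeometryError", "need at least 3 shared atoms to superpose")
  refXYZ <- .coordMatrix(ref)[subset, , drop = FALSE]
  movXYZ <- .coordMatrix(conf)[subset, , drop = FALSE]
  mass <- ra$mass[match(subset, ra$label)]
  ## collinearity guard: rank of the centered subset must exceed 1
  cm <- sweep(movXYZ, 2, colSums(movXYZ * mass) / sum(mass))
  if (sum(svd(cm)$d > 1e-8 * max(svd(cm)$d)) < 2)
    .err("rdcGeometryError", "superposition subset is collinear")
  k <- .kabsch(refXYZ, movXYZ, mass)
  all <- .coordMatrix(conf)
  newXYZ <- sweep(all, 2, k$centerMov) %*% t(k$R)
  newXYZ <- sweep(newXYZ, 2, k$centerRef, `+`)
  out <- conf
  out@atoms$x <- newXYZ[, 1]
  out@atoms$y <- newXYZ[, 2]
  out@atoms$z <- newXYZ[, 3]
  out
}

## Mass-weighted RMSD over a label subset (helper for tests/reports).
#' @rdname eckartSuperpose
#' @export
massWeightedRMSD <- function(ref, conf, subset = NULL) {
  ra <- atoms(ref); ca <- atoms(conf)
  if (is.null(subset)) subset <- intersect(ra$label, ca$label)
  a <- .coordMatrix(ref)[subset, , drop = FALSE]
  b <- .coordMatrix(conf)[subset, , drop = FALSE]
  m <- ra$mass[match(subset, ra$label)]
  sqrt(sum(m * rowSums((a - b)^2)) / sum(m))
}

#' Multi-conformer-single-tensor (MCST) fit
#'
#' Superposes all conformers onto the reference conformer's Eckart frame
#' and fits one common Saupe tensor to the population-weighted design
#' matrix: row i is the population-weighted sum over conformers of the
#' per-conformer rows. With a single conformer (or a degenerate
#' population vector) the result equals \code{\link{fitSCST}} exactly.
#'
#' @param confs list of \linkS4class{Conformer} sharing the labels used
#'   by \code{ds}.
#' @param pops population vector (non-negative, sums to 1 within 1e-9).
#' @param ds an \linkS4class{RDCDataset} with >= 5 included records.
#' @param refIndex index of the conformer defining the common frame;
#'   default is the lowest-energy conformer (first on ties/missing
#'   energies).
#' @param subset superposition subset, see \code{\link{eckartSuperpose}}.
#' @inheritParams fitSCST
#' @return an \linkS4class{RDCFit}.
#' @export
fitMCST <- function(confs, pops, ds, refIndex = NULL, weighted = TRUE,
                    sigmaFloor = 0.1, svCutoff = 1e-10,
                    fixedDistance = NULL, subset = NULL) {
  if (!is.list(confs)) confs <- list(confs)
  pops <- as.numeric(pops)
  if (length(pops) != length(confs))
    .err("rdcPopulationError", "one population per conformer is required")
  if (any(pops < 0) || abs(sum(pops) - 1) > 1e-9)
    .err("rdcPopulationError",
         "populations must be non-negative and sum to 1")
  if (is.null(refIndex)) {
    e <- vapply(confs, relEnergy, numeric(1))
    refIndex <- if (all(is.na(e))) 1L else which.min(e)
  }
  ref <- confs[[refIndex]]
  obs <- .observedRDCs(ds, sigmaFloor)
  if (nrow(obs$records) < 5)
    .err("rdcFitError", "at least 5 included records are required")
  A <- matrix(0, nrow(obs$records), 5)
  for (k in seq_along(confs)) {
    if (pops[k] == 0 && k != refIndex) next
    ck <- if (k == refIndex) confs[[k]]
          else eckartSuperpose(ref, confs[[k]], subset = subset)
    eff <- .resolveDataset(ck, ds, fixedDistance)
    Ak <- t(vapply(eff,
                   function(ev) .designRow(ev$unitVec, ev$kappa * ev$scale),
                   numeric(5)))
    A <- A + pops[k] * Ak
  }
  if (all(obs$d == 0))
    .err("rdcFitError", "all experimental RDCs are zero; nothing to fit")
  .finishFit(A, obs$d, 1 / obs$sig, obs$records, weighted, svCutoff)
}

#' Scan the two-conformer population against the Q factor
#'
#' Performs an MCST fit at every population of conformer 1 on the grid
#' \{0, step, ..., 1\} and locates the minimum of Q(p1). Ties are broken
#' toward the smallest p1.
#'
#' @param confs list of exactly two \linkS4class{Conformer}s.
#' @param ds an \linkS4class{RDCDataset}.
#' @param step grid increment in (0, 0.1]; default 0.01, matching the
#'   two-decimal precision conventionally reported for populations.
#' @inheritParams fitMCST
#' @return an \linkS4class{EnsembleFit}.
#' @export
scanPopulations <- function(confs, ds, step = 0.01, refIndex = NULL,
                            weighted = TRUE, sigmaFloor = 0.1,
                            svCutoff = 1e-10, fixedDistance = NULL,
                            subset = NULL) {
  if (length(confs) != 2)
    .err("rdcPopulationError", "the population scan takes exactly 2 conformers")
  if (step <= 0 || step > 0.1)
    .err("rdcPopulationError", "step must lie in (0, 0.1]")
  grid <- round(seq(0, 1, by = step), 10)
  if (grid[length(grid)] < 1) grid <- c(grid, 1)
  if (is.null(refIndex)) {
    e <- vapply(confs, relEnergy, numeric(1))
    refIndex <- if (all(is.na(e))) 1L else which.min(e)
  }
  ## the per-conformer design matrices do not depend on the population:
  ## resolve the geometry once and mix rows per grid point
  ref <- confs[[refIndex]]
  obs <- .observedRDCs(ds, sigmaFloor)
  if (nrow(obs$records) < 5)
    .err("rdcFitError", "at least 5 included records are required")
  if (all(obs$d == 0))
    .err("rdcFitError", "all experimental RDCs are zero; nothing to fit")
  Ak <- lapply(seq_along(confs), function(k) {
    ck <- if (k == refIndex) confs[[k]]
          else eckartSuperpose(ref, confs[[k]], subset = subset)
    eff <- .resolveDataset(ck, ds, fixedDistance)
    t(vapply(eff, function(ev) .designRow(ev$unitVec, ev$kappa * ev$scale),
             numeric(5)))
  })
  fits <- lapply(grid, function(p1)
    .finishFit(p1 * Ak[[1]] + (1 - p1) * Ak[[2]], obs$d, 1 / obs$sig,
               obs$records, weighted, svCutoff))
  qs <- vapply(fits, fitQ, numeric(1))
  ## tie rule: smallest p1 among Q values indistinguishable from the
  ## minimum (floating-point ties, e.g. exchange-symmetric conformers)
  best <- which(qs <= min(qs) + 1e-12 * (1 + min(qs)))[1]
  new("EnsembleFit", grid = grid, qCurve = qs, pBest = grid[best],
      fitBest = fits[[best]], fitP1 = fits[[length(grid)]],
      fitP0 = fits[[1]])
}
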