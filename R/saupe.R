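## Error-weighted SVD fitting of the Saupe order matrix to one rigid
## conformer (single-conformer-single-tensor, SCST).
##
## Unknown vector fixed as s = (S_xx, S_yy, S_xy, S_xz, S_yz) with
## S_zz = -S_xx - S_yy; this makes fits bit-reproducible.

#' Saupe tensor descriptors from a 3x3 order matrix
#'
#' Eigen-decomposes a symmetric traceless matrix, orders the principal
#' values by magnitude (|Szz'| >= |Syy'| >= |Sxx'|), and derives the
#' generalized degree of order \eqn{\sqrt{(2/3)\sum S_{ab}^2}}, the axial
#' component \eqn{D_a = S_{zz}'/2} and the rhombicity
#' \eqn{R = |2(S_{xx}' - S_{yy}')/(3 S_{zz}')|}. The principal-axis rotation is
#' returned with determinant +1.
#'
#' @param S symmetric traceless 3x3 matrix (tolerance 1e-10 relative).
#' @return a \linkS4class{SaupeTensor}.
#' @export
saupeTensor <- function(S) {
  S <- unname(as.matrix(S))
  if (!all(dim(S) == c(3, 3)))
    .err("rdcTensorError", "S must be a 3x3 matrix")
  nrm <- sqrt(sum(S^2))
  if (nrm > 0 && max(abs(S - t(S))) > 1e-10 * nrm)
    .err("rdcTensorError", "S must be symmetric")
  if (nrm > 0 && abs(sum(diag(S))) > 1e-10 * nrm)
    .err("rdcTensorError", "S must be traceless")
  S <- (S + t(S)) / 2
  S <- S - diag(sum(diag(S)) / 3, 3)   # exact symmetrization/detrace
  e <- eigen(S, symmetric = TRUE)
  ord <- order(abs(e$values))          # ascending: Sxx', Syy', Szz'
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  if (det(vecs) < 0) vecs[, 3] <- -vecs[, 3]
  szz <- vals[3]
  ## rhombicity R = Dr/Da = 2(Sxx' - Syy')/(3 Szz'), in [0, 2/3]
  new("SaupeTensor", S = S, eigvals = vals, eigvecs = vecs,
      gdo = sqrt(2 / 3 * sum(S^2)),
      Da = szz / 2,
      R = if (szz == 0) 0 else abs(2 * (vals[1] - vals[2]) / (3 * szz)))
}

#' Cornilescu quality factor
#'
#' \eqn{Q = \sqrt{\sum (D_{exp} - D_{calc})^2 / \sum D_{exp}^2}};
#' 0 means perfect agreement between experiment and structural model.
#'
#' @param dExp experimental RDCs (Hz).
#' @param dCalc back-calculated RDCs (Hz), same length.
#' @param weights optional per-record weights for the weighted variant;
#'   the default (NULL) is the standard unweighted definition.
#' @return dimensionless Q >= 0.
#' @export
qFactor <- function(dExp, dCalc, weights = NULL) {
  if (length(dExp) != length(dCalc) || length(dExp) < 1)
    .err("rdcQError", "dExp and dCalc must have equal positive length")
  if (all(dExp == 0))
    .err("rdcQError", "Q is undefined for all-zero experimental RDCs")
  if (is.null(weights)) weights <- rep(1, length(dExp))
  sqrt(sum((weights * (dExp - dCalc))^2) / sum((weights * dExp)^2))
}

## Effective D and sigD per included record: D directly, else (T-J)/2;
## sigD directly, else propagated, else the error floor.
.observedRDCs <- function(ds, sigmaFloor = 0.1) {
  r <- records(ds)
  r <- r[r$include, , drop = FALSE]
  d <- r$D
  conv <- is.na(d) & !is.na(r$J) & !is.na(r$T)
  d[conv] <- (r$T[conv] - r$J[conv]) / 2
  if (anyNA(d))
    .err("rdcFitError",
         sprintf("included record(s) %s carry neither D nor both J and T",
                 paste(which(is.na(d)), collapse = ", ")))
  sig <- r$sigD
  prop <- is.na(sig) & !is.na(r$sigJ) & !is.na(r$sigT)
  sig[prop] <- sqrt(r$sigJ[prop]^2 + r$sigT[prop]^2) / 2
  floored <- is.na(sig) | sig <= 0
  sig[floored] <- sigmaFloor
  list(records = r, d = d, sig = sig, flooredAny = any(floored))
}

## One design-matrix row from a unit vector e and prefactor kappa*scale.
.designRow <- function(e, k) {
  k * c(e[1]^2 - e[3]^2, e[2]^2 - e[3]^2,
        2 * e[1] * e[2], 2 * e[1] * e[3], 2 * e[2] * e[3])
}

#' Build the weighted linear system for a tensor fit
#'
#' Row i of A is \eqn{scale_i \kappa_i [e_x^2-e_z^2,\; e_y^2-e_z^2,\;
#' 2e_xe_y,\; 2e_xe_z,\; 2e_ye_z]} for unknowns
#' \eqn{(S_{xx}, S_{yy}, S_{xy}, S_{xz}, S_{yz})}; the right-hand side is
#' the experimental RDC vector and the weights are 1/sigD (with an error
#' floor for records lacking an error estimate).
#'
#' @param conf a \linkS4class{Conformer}.
#' @param ds an \linkS4class{RDCDataset} with >= 5 included records.
#' @param sigmaFloor error floor in Hz for records without sigD
#'   (default 0.1).
#' @param fixedDistance see \code{\link{effectiveVector}}.
#' @return list with \code{A} (n x 5), \code{d} (n), \code{w} (n) and the
#'   resolved record table \code{records}. Rank deficiency of A is not an
#'   error here; it is reported by the fit's condition number.
#' @export
buildDesignMatrix <- function(conf, ds, sigmaFloor = 0.1,
                              fixedDistance = NULL) {
  obs <- .observedRDCs(ds, sigmaFloor)
  if (nrow(obs$records) < 5)
    .err("rdcFitError", "at least 5 included records are required")
  eff <- .resolveDataset(conf, ds, fixedDistance)
  A <- t(vapply(eff, function(ev) .designRow(ev$unitVec, ev$kappa * ev$scale),
                numeric(5)))
  list(A = A, d = obs$d, w = 1 / obs$sig, records = obs$records,
       flooredAny = obs$flooredAny)
}

## Truncated-SVD least squares of diag(w) A s = diag(w) d.
.svdSolve <- function(A, d, w, svCutoff = 1e-10) {
  WA <- A * w
  sv <- svd(WA)
  keep <- sv$d > svCutoff * max(sv$d)
  inv <- ifelse(keep, 1 / sv$d, 0)
  s <- sv$v %*% (inv * (t(sv$u) %*% (w * d)))
  list(s = drop(s), singvals = sv$d,
       condition = if (all(keep)) max(sv$d) / min(sv$d) else Inf,
       rankDeficient = !all(keep))
}

.vecToS <- function(s) {
  matrix(c(s[1], s[3], s[4],
           s[3], s[2], s[5],
           s[4], s[5], -s[1] - s[2]), 3, 3)
}

.finishFit <- function(A, d, w, recs, weighted, svCutoff) {
  sol <- .svdSolve(A, d, if (weighted) w else rep(1, length(d)), svCutoff)
  dCalc <- drop(A %*% sol$s)
  res <- d - dCalc
  if (sol$rankDeficient)
    warning("design matrix rank deficient at the SVD cutoff; ",
            "minimum-norm solution returned", call. = FALSE)
  tab <- data.frame(atom1 = recs$atom1, atom2 = recs$atom2,
                    type = recs$type, dExp = d, sigD = 1 / w,
                    dCalc = dCalc, residual = res,
                    stringsAsFactors = FALSE)
  new("RDCFit", tensor = saupeTensor(.vecToS(sol$s)), records = tab,
      q = qFactor(d, dCalc), qWeighted = qFactor(d, dCalc, weights = w),
      rmsd = sqrt(mean(res^2)), singvals = sol$singvals,
      condition = sol$condition, weighted = weighted,
      rankDeficient = sol$rankDeficient)
}

#' Single-conformer-single-tensor (SCST) fit
#'
#' Solves the error-weighted linear system for the five independent
#' Saupe matrix elements by truncated singular value decomposition and
#' back-calculates the RDCs. The quality factor Q is reported unweighted
#' (Cornilescu's definition) even for weighted fits; the weighted variant
#' is available from the \code{qWeighted} slot.
#'
#' @param conf a \linkS4class{Conformer} (the rigid structural model).
#' @param ds an \linkS4class{RDCDataset} with >= 5 included records.
#' @param weighted scale rows by 1/sigD (default TRUE).
#' @param sigmaFloor error floor (Hz) for records lacking sigD.
#' @param svCutoff relative singular-value cutoff for the pseudo-inverse.
#' @param fixedDistance see \code{\link{effectiveVector}}.
#' @return an \linkS4class{RDCFit}.
#' @examples
#' sim <- makeRigidMolecule(simulationSpec(nVectors = 10, seed = 7))
#' S <- randomSaupe(5e-4, seed = 7)
#' ds <- simulateRDCs(sim$conformer, S, spec = simulationSpec(
#'   nVectors = 10, noiseSigma = 0, seed = 7))
#' fit <- fitSCST(sim$conformer, ds)
#' fitQ(fit)  # ~0 for noiseless data
#' @export
fitSCST <- function(conf, ds, weighted = TRUE, sigmaFloor = 0.1,
                    svCutoff = 1e-10, fixedDistance = NULL) {
  sys <- buildDesignMatrix(conf, ds, sigmaFloor, fixedDistance)
  if (all(sys$d == 0))
    .err("rdcFitError", "all experimental RDCs are zero; nothing to fit")
  .finishFit(sys$A, sys$d, sys$w, sys$records, weighted, svCutoff)
}
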