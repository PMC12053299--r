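## Coupling-to-RDC conversion and per-record geometric/physical factors.
##
## Convention: the total one-bond splitting is 1T = 1J + 2 * 1D, so
## D = (T - J)/2, and the dipolar prefactor uses h (not hbar) such that
## full order along the bond contributes a splitting of 2D equal to the
## static dipolar splitting. The absolute scale cancels in Q for
## single-coupling-type datasets.

#' Extract an RDC from scalar and total couplings
#'
#' Applies \eqn{D = (T - J)/2} with Gaussian error propagation
#' \eqn{\sigma_D = \sqrt{\sigma_J^2 + \sigma_T^2}/2}.
#'
#' @param J scalar coupling (Hz).
#' @param sigJ error on J (Hz), optional.
#' @param T total coupling in the aligned phase (Hz).
#' @param sigT error on T (Hz), optional.
#' @return list with components \code{D} and \code{sigD} (Hz; \code{sigD}
#'   is NA when either error is absent). Vectorized over records.
#' @examples
#' extractRDC(125.0, 0.2, 145.0, 0.3)  # D = 10 Hz, sigD ~ 0.18 Hz
#' @export
extractRDC <- function(J, sigJ = NA_real_, T, sigT = NA_real_) {
  if (missing(J) || missing(T) || anyNA(J) || anyNA(T))
    .err("rdcConversionError",
         "both J and T are required to extract an RDC")
  stopifnot(all(is.na(sigJ) | sigJ > 0), all(is.na(sigT) | sigT > 0))
  list(D = (T - J) / 2, sigD = sqrt(sigJ^2 + sigT^2) / 2)
}

#' Dipolar coupling prefactor
#'
#' \eqn{\kappa = -\mu_0 \gamma_i \gamma_j h / (16 \pi^3 r^3)} in Hz with
#' the internuclear distance r converted to metres internally. Negative
#' for two positive-gamma nuclei (e.g. 13C-1H at 1.09 Angstrom gives
#' about -2.33e4 Hz).
#'
#' @param ctype coupling class (\code{"CH"}, \code{"CH2-member"} and
#'   \code{"CH3-methyl"} are carbon-proton; \code{"CC"} carbon-carbon;
#'   \code{"generic"} defaults to carbon-proton).
#' @param r internuclear distance (Angstrom).
#' @return prefactor in Hz.
#' @export
dipolarPrefactor <- function(ctype, r) {
  stopifnot(all(r > 0))
  nuc <- switch(ctype,
    "CH" = , "CH2-member" = , "CH3-methyl" = , "generic" = c("C", "H"),
    "CC" = c("C", "C"),
    .err("rdcNucleusError", paste("unsupported coupling class:", ctype)))
  g1 <- gyromagneticRatio(nuc[1]); g2 <- gyromagneticRatio(nuc[2])
  rm <- r * 1e-10
  -(.MU0 * g1 * g2 * .PLANCK_H) / (16 * pi^3 * rm^3)
}

## Bonded-neighbour search used for methyl records only: H within
## 1.3 A of the methyl carbon, heavy neighbour within 1.85 A.
.methylGeometry <- function(conf, cLabel) {
  a <- atoms(conf)
  xyz <- .coordMatrix(conf)
  ci <- match(cLabel, a$label)
  d <- sqrt(rowSums((xyz - matrix(xyz[ci, ], nrow(xyz), 3, byrow = TRUE))^2))
  hs <- which(a$element == "H" & d > 0 & d < 1.3)
  heavy <- which(a$element != "H" & d > 0 & d < 1.85)
  if (length(hs) != 3 || length(heavy) < 1)
    .err("rdcMethylError",
         sprintf("atom %s is not a methyl carbon with an identifiable axis",
                 cLabel))
  list(h = hs, axisAtom = heavy[which.min(d[heavy])], ci = ci, xyz = xyz)
}

#' Geometric and physical factors of one coupling record
#'
#' For rigid pairs the internuclear unit vector runs atom1 to atom2 with
#' averaging factor 1. For methyl (\code{CH3-methyl}) records the
#' effective vector is the C(methyl) to C(neighbour) rotation axis and
#' the averaging factor is \eqn{P_2(\cos\theta)} averaged over the three
#' proton positions (about -1/3 for ideal tetrahedral geometry), with the
#' prefactor computed from the mean C-H distance.
#'
#' @param conf a \linkS4class{Conformer}.
#' @param rec one-row data.frame (a row of \code{records(ds)}).
#' @param fixedDistance optional named numeric vector mapping coupling
#'   classes to a fixed effective distance (Angstrom) overriding the
#'   coordinate-derived r.
#' @return list with \code{unitVec} (3-unit-vector, conformer frame),
#'   \code{kappa} (Hz), \code{scale} (dimensionless, in [-1, 1]) and
#'   \code{r} (Angstrom).
#' @export
effectiveVector <- function(conf, rec, fixedDistance = NULL) {
  a <- atoms(conf)
  i <- match(rec$atom1, a$label); j <- match(rec$atom2, a$label)
  if (is.na(i) || is.na(j))
    .err("rdcLabelError",
         sprintf("atom label(s) %s not found in conformer %s",
                 paste(c(rec$atom1, rec$atom2)[c(is.na(i), is.na(j))],
                       collapse = ", "), conf@id))
  xyz <- .coordMatrix(conf)
  if (identical(rec$type, "CH3-methyl")) {
    ## atom1 is the methyl carbon; the axis runs to its heavy neighbour
    mg <- .methylGeometry(conf, rec$atom1)
    axis <- xyz[mg$axisAtom, ] - xyz[mg$ci, ]
    axis <- axis / sqrt(sum(axis^2))
    ch <- xyz[mg$h, , drop = FALSE] -
      matrix(xyz[mg$ci, ], 3, 3, byrow = TRUE)
    rch <- sqrt(rowSums(ch^2))
    cosTheta <- (ch %*% axis) / rch
    scale <- mean((3 * cosTheta^2 - 1) / 2)
    r <- mean(rch)
    if (!is.null(fixedDistance) && rec$type %in% names(fixedDistance))
      r <- fixedDistance[[rec$type]]
    return(list(unitVec = axis, kappa = dipolarPrefactor(rec$type, r),
                scale = scale, r = r))
  }
  v <- xyz[j, ] - xyz[i, ]
  r <- sqrt(sum(v^2))
  if (r == 0) .err("rdcGeometryError", "coincident atoms in coupling record")
  if (!is.null(fixedDistance) && rec$type %in% names(fixedDistance)) {
    rEff <- fixedDistance[[rec$type]]
  } else rEff <- r
  list(unitVec = v / r, kappa = dipolarPrefactor(rec$type, rEff),
       scale = 1, r = rEff)
}

## Resolve all included records of a dataset against one conformer.
## Returns a list of effectiveVector() results, in record order.
.resolveDataset <- function(conf, ds, fixedDistance = NULL) {
  r <- records(ds)
  r <- r[r$include, , drop = FALSE]
  lapply(seq_len(nrow(r)),
         function(i) effectiveVector(conf, r[i, , drop = FALSE],
                                     fixedDistance))
}
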