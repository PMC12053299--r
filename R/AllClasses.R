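#' @import methods
#' @importFrom stats rnorm
#' @importFrom jsonlite toJSON fromJSON
#' @importFrom utils head
NULL

## Canonical coupling classes accepted in RDC tables.
.CTYPES <- c("CH", "CH2-member", "CH3-methyl", "CC", "generic")

#' Conformer: a named molecular geometry
#'
#' A single conformer holds an ordered atom table (label, element, mass,
#' Cartesian coordinates in Angstrom) and an optional relative energy in
#' kcal/mol. Atom labels are the join key against coupling tables; they
#' must be unique within a conformer.
#'
#' @slot id character identifier of the conformer.
#' @slot atoms data.frame with columns \code{label}, \code{element},
#'   \code{mass} (u), \code{x}, \code{y}, \code{z} (Angstrom).
#' @slot eRel relative energy in kcal/mol (\code{NA_real_} if unknown).
#'
#' @exportClass Conformer
setClass("Conformer",
  representation(id = "character", atoms = "data.frame", eRel = "numeric"),
  prototype(id = "conf", eRel = NA_real_)
)

setValidity("Conformer", function(object) {
  a <- object@atoms
  need <- c("label", "element", "mass", "x", "y", "z")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) < 2) return("a Conformer needs at least 2 atoms")
  if (anyDuplicated(a$label)) return("atom labels must be unique")
  if (any(!is.finite(a$mass)) || any(a$mass <= 0))
    return("all atomic masses must be positive and finite")
  if (any(!is.finite(as.matrix(a[, c("x", "y", "z")]))))
    return("coordinates must be finite")
  if (length(object@eRel) != 1) return("eRel must be length 1")
  TRUE
})

#' RDCDataset: a table of coupling measurements
#'
#' One row per atom-pair measurement carrying any of the scalar coupling
#' \code{J}, total coupling \code{T} and dipolar coupling \code{D} (all Hz)
#' with their experimental errors. Records flagged \code{include = FALSE}
#' are carried through I/O but excluded from fits.
#'
#' @slot records data.frame with columns \code{atom1}, \code{atom2},
#'   \code{type}, \code{J}, \code{sigJ}, \code{T}, \code{sigT}, \code{D},
#'   \code{sigD}, \code{include}.
#' @slot meta list of free-form provenance (medium, concentration,
#'   temperature, ...).
#'
#' @exportClass RDCDataset
setClass("RDCDataset",
  representation(records = "data.frame", meta = "list"),
  prototype(meta = list())
)

setValidity("RDCDataset", function(object) {
  r <- object@records
  need <- c("atom1", "atom2", "type", "J", "sigJ", "T", "sigT", "D",
            "sigD", "include")
  if (!all(need %in% names(r)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  if (nrow(r) > 0) {
    if (!all(r$type %in% .CTYPES))
      return(paste("unknown coupling type(s):",
                   paste(setdiff(unique(r$type), .CTYPES), collapse = ", ")))
    hasAny <- !is.na(r$D) | !is.na(r$J) | !is.na(r$T)
    if (any(!hasAny))
      return("every record needs at least one coupling value")
    for (s in c("sigJ", "sigT", "sigD")) {
      v <- r[[s]]
      if (any(!is.na(v) & v <= 0))
        return(paste(s, "must be positive where present"))
    }
  }
  TRUE
})

#' SaupeTensor: the alignment (order) tensor and derived descriptors
#'
#' Symmetric traceless 3x3 Saupe order matrix together with its principal
#' values ordered by decreasing magnitude, the rotation to the principal
#' axis frame (det +1), the generalized degree of order
#' \eqn{GDO = \sqrt{(2/3)\sum_{ab} S_{ab}^2}}, the axial component
#' \eqn{D_a = S_{zz}'/2} and the rhombicity
#' \eqn{R = |2(S_{xx}' - S_{yy}')/(3 S_{zz}')|}.
#'
#' @slot S symmetric traceless 3x3 matrix (dimensionless).
#' @slot eigvals numeric(3), principal values with |Szz'| >= |Syy'| >= |Sxx'|
#'   stored in the order (Sxx', Syy', Szz').
#' @slot eigvecs 3x3 proper rotation whose columns are the principal axes.
#' @slot gdo generalized degree of order.
#' @slot Da axial component Szz'/2.
#' @slot R rhombicity, in [0, 2/3] under the magnitude ordering.
#'
#' @exportClass SaupeTensor
setClass("SaupeTensor",
  representation(S = "matrix", eigvals = "numeric", eigvecs = "matrix",
                 gdo = "numeric", Da = "numeric", R = "numeric")
)

setValidity("SaupeTensor", function(object) {
  S <- object@S
  if (!all(dim(S) == c(3, 3))) return("S must be 3x3")
  if (!isTRUE(all.equal(S, t(S), tolerance = 0, check.attributes = FALSE)) &&
      max(abs(S - t(S))) > 0)
    return("S must be exactly symmetric")
  nrm <- sqrt(sum(S^2))
  if (nrm > 0 && abs(sum(diag(S))) > 1e-10 * nrm)
    return("S must be traceless")
  if (object@gdo < 0) return("gdo must be non-negative")
  TRUE
})

#' RDCFit: result of a single-tensor fit
#'
#' Holds the fitted tensor, experimental and back-calculated RDCs,
#' residuals, the unweighted Cornilescu quality factor Q, the rms residual,
#' the five singular values of the weighted design matrix and their
#' condition ratio.
#'
#' @slot tensor fitted \linkS4class{SaupeTensor}.
#' @slot records data.frame of the fitted records (atom1, atom2, type,
#'   dExp, sigD, dCalc, residual).
#' @slot q Cornilescu quality factor (unweighted).
#' @slot qWeighted error-weighted variant of Q.
#' @slot rmsd root-mean-square residual (Hz).
#' @slot singvals numeric(5), singular values of the weighted design matrix.
#' @slot condition ratio largest/smallest singular value (+Inf if rank
#'   deficient at the cutoff).
#' @slot weighted logical, whether rows were scaled by 1/sigD.
#' @slot rankDeficient logical flag set when singular values fell below the
#'   relative cutoff.
#'
#' @exportClass RDCFit
setClass("RDCFit",
  representation(tensor = "SaupeTensor", records = "data.frame",
                 q = "numeric", qWeighted = "numeric", rmsd = "numeric",
                 singvals = "numeric", condition = "numeric",
                 weighted = "logical", rankDeficient = "logical")
)

setValidity("RDCFit", function(object) {
  r <- object@records
  need <- c("atom1", "atom2", "dExp", "sigD", "dCalc", "residual")
  if (!all(need %in% names(r)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  if (object@q < 0 || object@rmsd < 0) return("q and rmsd must be >= 0")
  TRUE
})

#' EnsembleFit: population scan of a two-conformer MCST fit
#'
#' @slot grid populations of conformer 1 scanned (strictly increasing,
#'   within [0, 1]).
#' @slot qCurve Q factor at each grid point.
#' @slot pBest grid argmin of Q (ties broken toward the smallest p1).
#' @slot fitBest \linkS4class{RDCFit} at pBest.
#' @slot fitP1 fit at p1 = 1 (conformer 1 alone).
#' @slot fitP0 fit at p1 = 0 (conformer 2 alone).
#'
#' @exportClass EnsembleFit
setClass("EnsembleFit",
  representation(grid = "numeric", qCurve = "numeric", pBest = "numeric",
                 fitBest = "RDCFit", fitP1 = "RDCFit", fitP0 = "RDCFit")
)

setValidity("EnsembleFit", function(object) {
  g <- object@grid
  if (any(g < 0 | g > 1)) return("grid must lie in [0, 1]")
  if (any(diff(g) <= 0)) return("grid must be strictly increasing")
  if (length(object@qCurve) != length(g))
    return("qCurve must match grid length")
  TRUE
})

#' TensorComparison: 5D angle between two alignment tensors
#'
#' @slot betaDeg generalized angle in degrees, within [0, 180].
#' @slot gdoRatio ratio gdo1/gdo2 of the two tensors.
#' @slot frameNote text recording whether a mirror convention was applied.
#'
#' @exportClass TensorComparison
setClass("TensorComparison",
  representation(betaDeg = "numeric", gdoRatio = "numeric",
                 frameNote = "character")
)

setValidity("TensorComparison", function(object) {
  if (object@betaDeg < 0 || object@betaDeg > 180)
    return("betaDeg must be in [0, 180]")
  if (object@gdoRatio <= 0) return("gdoRatio must be positive")
  TRUE
})

#' PopulationTable: conformer energies, populations and grouping
#'
#' Mirrors the bookkeeping applied to conformer ensembles: raw
#' (Boltzmann-weighted) populations per conformer, a user-supplied mapping
#' of conformers to groups sharing the conformation of the analysed part,
#' combined populations per group and populations normalized over the
#' retained groups.
#'
#' @slot conformers data.frame with columns \code{conf} (id), \code{eRel}
#'   (kcal/mol), \code{pRaw}, \code{group} (NA until assigned),
#'   \code{retained} (logical).
#' @slot groups data.frame with columns \code{group}, \code{pComb},
#'   \code{pNorm} (empty until \code{combineAndNormalize}).
#'
#' @exportClass PopulationTable
setClass("PopulationTable",
  representation(conformers = "data.frame", groups = "data.frame"),
  prototype(groups = data.frame(group = character(), pComb = numeric(),
                                pNorm = numeric()))
)

setValidity("PopulationTable", function(object) {
  cf <- object@conformers
  need <- c("conf", "eRel", "pRaw", "group", "retained")
  if (!all(need %in% names(cf)))
    return(paste("conformers must have columns:", paste(need, collapse = ", ")))
  if (nrow(cf) > 0 && any(!is.na(cf$pRaw) & cf$pRaw < 0))
    return("raw populations must be non-negative")
  g <- object@groups
  if (nrow(g) > 0) {
    if (any(g$pComb < 0) || any(g$pNorm < 0))
      return("group populations must be non-negative")
    if (abs(sum(g$pNorm) - 1) > 1e-9)
      return("normalized populations must sum to 1")
  }
  TRUE
})

## ---- show methods ----------------------------------------------------

setMethod("show", "Conformer", function(object) {
  cat("Conformer", sQuote(object@id), "with", nrow(object@atoms), "atoms")
  if (!is.na(object@eRel)) cat(sprintf("; E_rel = %.3f kcal/mol", object@eRel))
  cat("\n")
  counts <- table(object@atoms$element)
  cat("  composition:",
      paste0(names(counts), counts, collapse = " "), "\n")
})

setMethod("show", "RDCDataset", function(object) {
  r <- object@records
  cat("RDCDataset with", nrow(r), "records (",
      sum(r$include), "included )\n")
  if (nrow(r) > 0) {
    cat("  types:", paste(unique(r$type), collapse = ", "), "\n")
    if (any(!is.na(r$D)))
      cat(sprintf("  D range: %.2f to %.2f Hz\n",
                  min(r$D, na.rm = TRUE), max(r$D, na.rm = TRUE)))
  }
})

setMethod("show", "SaupeTensor", function(object) {
  cat("SaupeTensor\n")
  cat(sprintf("  principal values: %.3e %.3e %.3e\n",
              object@eigvals[1], object@eigvals[2], object@eigvals[3]))
  cat(sprintf("  GDO = %.3e, Da = %.3e, R = %.3f\n",
              object@gdo, object@Da, object@R))
})

setMethod("show", "RDCFit", function(object) {
  cat("RDCFit on", nrow(object@records), "RDCs",
      if (object@weighted) "(error-weighted)" else "(unweighted)", "\n")
  cat(sprintf("  Q = %.4f, rmsd = %.3f Hz, condition = %.3g\n",
              object@q, object@rmsd, object@condition))
  if (object@rankDeficient)
    cat("  WARNING: design matrix rank deficient at the SVD cutoff\n")
})

setMethod("show", "EnsembleFit", function(object) {
  cat("EnsembleFit: population scan over", length(object@grid), "points\n")
  cat(sprintf("  Q(p1=1) = %.4f, Q(p1=0) = %.4f\n",
              object@fitP1@q, object@fitP0@q))
  cat(sprintf("  minimum: Q(%.2f) = %.4f\n", object@pBest,
              min(object@qCurve)))
})

setMethod("show", "TensorComparison", function(object) {
  cat(sprintf("TensorComparison: beta = %.2f deg, gdo ratio = %.3f\n",
              object@betaDeg, object@gdoRatio))
  if (nzchar(object@frameNote)) cat(" ", object@frameNote, "\n")
})

setMethod("show", "PopulationTable", function(object) {
  cf <- object@conformers
  cat("PopulationTable with", nrow(cf), "conformers (",
      sum(cf$retained), "retained )\n")
  if (nrow(object@groups) > 0) {
    g <- object@groups
    cat("  groups:\n")
    for (i in seq_len(nrow(g)))
      cat(sprintf("    %s: p_comb = %.4f, p_norm = %.4f\n",
                  g$group[i], g$pComb[i], g$pNorm[i]))
  }
})
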