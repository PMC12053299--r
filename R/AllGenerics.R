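## Accessor generics. Slots are never reached into by user code.

#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @export
setGeneric("relEnergy", function(x) standardGeneric("relEnergy"))
#' @export
setGeneric("records", function(x) standardGeneric("records"))
#' @export
setGeneric("saupeMatrix", function(x) standardGeneric("saupeMatrix"))
#' @export
setGeneric("principalValues", function(x) standardGeneric("principalValues"))
#' @export
setGeneric("principalAxes", function(x) standardGeneric("principalAxes"))
#' @export
setGeneric("gdo", function(x) standardGeneric("gdo"))
#' @export
setGeneric("axialComponent", function(x) standardGeneric("axialComponent"))
#' @export
setGeneric("rhombicity", function(x) standardGeneric("rhombicity"))
#' @export
setGeneric("fitQ", function(x) standardGeneric("fitQ"))
#' @export
setGeneric("fitTensor", function(x) standardGeneric("fitTensor"))
#' @export
setGeneric("scanGrid", function(x) standardGeneric("scanGrid"))
#' @export
setGeneric("qCurve", function(x) standardGeneric("qCurve"))
#' @export
setGeneric("bestPopulation", function(x) standardGeneric("bestPopulation"))
#' @export
setGeneric("bestFit", function(x) standardGeneric("bestFit"))
#' @export
setGeneric("endpointFits", function(x) standardGeneric("endpointFits"))
#' @export
setGeneric("betaDegrees", function(x) standardGeneric("betaDegrees"))
#' @export
setGeneric("conformerTable", function(x) standardGeneric("conformerTable"))
#' @export
setGeneric("groupTable", function(x) standardGeneric("groupTable"))

#' Accessors for rdctensor classes
#'
#' Extract components of \linkS4class{Conformer}, \linkS4class{RDCDataset},
#' \linkS4class{SaupeTensor}, \linkS4class{RDCFit},
#' \linkS4class{EnsembleFit}, \linkS4class{TensorComparison} and
#' \linkS4class{PopulationTable} objects.
#'
#' @param x an rdctensor object.
#' @return \code{atoms} and the table accessors return data.frames;
#'   the scalar accessors return numeric values; \code{saupeMatrix} and
#'   \code{principalAxes} return 3x3 matrices; \code{fitTensor} a
#'   \linkS4class{SaupeTensor}; \code{bestFit} and \code{endpointFits}
#'   \linkS4class{RDCFit} objects.
#'
#' @name accessors
#' @aliases atoms relEnergy records saupeMatrix principalValues
#'   principalAxes gdo axialComponent rhombicity fitQ fitTensor scanGrid
#'   qCurve bestPopulation bestFit endpointFits betaDegrees conformerTable
#'   groupTable
NULL

#' @rdname accessors
#' @export
setMethod("atoms", "Conformer", function(x) x@atoms)
#' @rdname accessors
#' @export
setMethod("relEnergy", "Conformer", function(x) x@eRel)
#' @rdname accessors
#' @export
setMethod("records", "RDCDataset", function(x) x@records)
#' @rdname accessors
#' @export
setMethod("records", "RDCFit", function(x) x@records)
#' @rdname accessors
#' @export
setMethod("saupeMatrix", "SaupeTensor", function(x) x@S)
#' @rdname accessors
#' @export
setMethod("principalValues", "SaupeTensor", function(x) x@eigvals)
#' @rdname accessors
#' @export
setMethod("principalAxes", "SaupeTensor", function(x) x@eigvecs)
#' @rdname accessors
#' @export
setMethod("gdo", "SaupeTensor", function(x) x@gdo)
#' @rdname accessors
#' @export
setMethod("axialComponent", "SaupeTensor", function(x) x@Da)
#' @rdname accessors
#' @export
setMethod("rhombicity", "SaupeTensor", function(x) x@R)
#' @rdname accessors
#' @export
setMethod("fitQ", "RDCFit", function(x) x@q)
#' @rdname accessors
#' @export
setMethod("fitTensor", "RDCFit", function(x) x@tensor)
#' @rdname accessors
#' @export
setMethod("scanGrid", "EnsembleFit", function(x) x@grid)
#' @rdname accessors
#' @export
setMethod("qCurve", "EnsembleFit", function(x) x@qCurve)
#' @rdname accessors
#' @export
setMethod("bestPopulation", "EnsembleFit", function(x) x@pBest)
#' @rdname accessors
#' @export
setMethod("bestFit", "EnsembleFit", function(x) x@fitBest)
#' @rdname accessors
#' @export
setMethod("endpointFits", "EnsembleFit",
          function(x) list(p1 = x@fitP1, p0 = x@fitP0))
#' @rdname accessors
#' @export
setMethod("betaDegrees", "TensorComparison", function(x) x@betaDeg)
#' @rdname accessors
#' @export
setMethod("conformerTable", "PopulationTable", function(x) x@conformers)
#' @rdname accessors
#' @export
setMethod("groupTable", "PopulationTable", function(x) x@groups)
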