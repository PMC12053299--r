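## JSON and aligned-text reports for fits, scans and comparisons.

.tensorToList <- function(tn) {
  list(S = saupeMatrix(tn),
       eigvals = principalValues(tn),
       eigvecs = principalAxes(tn),
       gdo = gdo(tn), Da = axialComponent(tn), R = rhombicity(tn))
}

#' Serialize fit results to JSON
#'
#' @param x an \linkS4class{RDCFit}, \linkS4class{EnsembleFit} or
#'   \linkS4class{TensorComparison}.
#' @param path optional output file; when NULL the JSON string is
#'   returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
fitReportJSON <- function(x, path = NULL) {
  payload <-
    if (is(x, "RDCFit")) {
      list(kind = "scst",
           tensor = .tensorToList(fitTensor(x)),
           records = records(x),
           q = fitQ(x), qWeighted = x@qWeighted, rmsd = x@rmsd,
           singvals = x@singvals, condition = x@condition,
           weighted = x@weighted, rankDeficient = x@rankDeficient)
    } else if (is(x, "EnsembleFit")) {
      ep <- endpointFits(x)
      list(kind = "mcst-scan",
           grid = scanGrid(x), qCurve = qCurve(x),
           pBest = bestPopulation(x), qBest = fitQ(bestFit(x)),
           fitBest = jsonlite::fromJSON(fitReportJSON(bestFit(x))),
           qP1 = fitQ(ep$p1), qP0 = fitQ(ep$p0))
    } else if (is(x, "TensorComparison")) {
      list(kind = "comparison", betaDeg = betaDegrees(x),
           gdoRatio = x@gdoRatio, frameNote = x@frameNote)
    } else .err("rdcReportError", "unsupported object for fitReportJSON")
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(as.character(js))
}

#' Aligned-text report of a fit
#'
#' @param x an \linkS4class{RDCFit} or \linkS4class{EnsembleFit}.
#' @param path optional output file; NULL prints to the console.
#' @return the report lines, invisibly when written.
#' @export
fitReportText <- function(x, path = NULL) {
  lines <- character()
  if (is(x, "RDCFit")) {
    tn <- fitTensor(x)
    lines <- c(lines,
      "RDC tensor fit",
      sprintf("  records: %d   weighted: %s", nrow(records(x)),
              x@weighted),
      sprintf("  Q = %.4f   rmsd = %.3f Hz   condition = %.4g",
              fitQ(x), x@rmsd, x@condition),
      sprintf("  GDO = %.4e   Da = %.4e   R = %.4f",
              gdo(tn), axialComponent(tn), rhombicity(tn)),
      "",
      sprintf("  %-6s %-6s %10s %8s %10s %10s",
              "atom1", "atom2", "D_exp", "sigD", "D_calc", "residual"))
    r <- records(x)
    lines <- c(lines, sprintf("  %-6s %-6s %10.3f %8.3f %10.3f %10.3f",
                              r$atom1, r$atom2, r$dExp, r$sigD, r$dCalc,
                              r$residual))
  } else if (is(x, "EnsembleFit")) {
    ep <- endpointFits(x)
    lines <- c(lines,
      "MCST population scan",
      sprintf("  Q(p1=1.00) = %.4f   Q(p1=0.00) = %.4f",
              fitQ(ep$p1), fitQ(ep$p0)),
      sprintf("  minimum: Q(%.2f) = %.4f", bestPopulation(x),
              fitQ(bestFit(x))),
      "", "  p1       Q",
      sprintf("  %.2f  %.6f", scanGrid(x), qCurve(x)))
  } else .err("rdcReportError", "unsupported object for fitReportText")
  if (is.null(path)) { cat(lines, sep = "\n"); return(invisible(lines)) }
  writeLines(lines, path)
  invisible(lines)
}

#' Two-column Q(p) table of a population scan
#'
#' @param x an \linkS4class{EnsembleFit}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeQCurve <- function(x, path) {
  writeLines(c("p1\tQ", sprintf("%.4f\t%.8f", scanGrid(x), qCurve(x))),
             path)
  invisible(path)
}
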