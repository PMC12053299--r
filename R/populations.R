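## Boltzmann weighting, conformer grouping/combination, pruning and
## normalization of conformer populations.
##
## Raw populations (e.g. from a conformer-sampling tool) are accepted as
## input rather than recomputed from relative energies: sampled
## populations can include rotamer degeneracies that pure Boltzmann
## factors of the printed energies do not reproduce. boltzmannPopulations
## is provided for synthetic work.

#' Construct a PopulationTable
#'
#' @param conf conformer identifiers.
#' @param eRel relative energies (kcal/mol), NA allowed.
#' @param pRaw raw (Boltzmann-weighted) populations.
#' @param group group labels (NA for unassigned).
#' @return a \linkS4class{PopulationTable} with all conformers retained.
#' @export
populationTable <- function(conf, eRel = NA_real_, pRaw, group = NA_character_) {
  n <- length(conf)
  new("PopulationTable",
      conformers = data.frame(conf = as.character(conf),
                              eRel = rep_len(as.numeric(eRel), n),
                              pRaw = as.numeric(pRaw),
                              group = rep_len(as.character(group), n),
                              retained = TRUE,
                              stringsAsFactors = FALSE))
}

#' Boltzmann populations from relative energies
#'
#' \eqn{p_i = \exp(-E_i/k_BT) / \sum_j \exp(-E_j/k_BT)} with
#' \eqn{k_B = 0.0019872041} kcal/(mol K), computed with the max-shift
#' trick for numerical stability.
#'
#' @param eRel relative energies (kcal/mol).
#' @param temperature temperature in K (default 298.15).
#' @return population vector summing to 1.
#' @export
boltzmannPopulations <- function(eRel, temperature = 298.15) {
  if (length(eRel) == 0) .err("rdcPopulationError", "empty energy vector")
  stopifnot(all(is.finite(eRel)), temperature > 0)
  x <- -eRel / (.KB_KCAL * temperature)
  x <- x - max(x)
  exp(x) / sum(exp(x))
}

#' Prune high-energy, low-population conformers
#'
#' Removes conformers satisfying BOTH \code{eRel > eMax} and
#' \code{pRaw < pMin} (conjunctive rule); a conformer failing only one
#' condition is retained. Defaults: eMax 2.2 kcal/mol, pMin 1 %.
#'
#' @param tbl a \linkS4class{PopulationTable} with eRel and pRaw.
#' @param eMax energy cutoff (kcal/mol).
#' @param pMin population cutoff (fraction).
#' @return the table with the \code{retained} flag updated.
#' @export
pruneConformers <- function(tbl, eMax = 2.2, pMin = 0.01) {
  cf <- conformerTable(tbl)
  drop <- !is.na(cf$eRel) & cf$eRel > eMax & cf$pRaw < pMin
  if (all(drop)) .err("rdcPopulationError", "pruning would remove all conformers")
  cf$retained <- !drop
  tbl@conformers <- cf
  tbl
}

#' Assign conformers to groups
#'
#' Groups collect conformers that share the conformation of the part of
#' the molecule used for RDC analysis (a chemical judgement supplied by
#' the user, not inferred).
#'
#' @param tbl a \linkS4class{PopulationTable}.
#' @param groups named list of character vectors, e.g.
#'   \code{list(A = c("01", "02"), B = c("03", "04"))}.
#' @return the table with group labels assigned.
#' @export
assignGroups <- function(tbl, groups) {
  cf <- conformerTable(tbl)
  for (g in names(groups)) {
    idx <- match(groups[[g]], cf$conf)
    if (anyNA(idx))
      .err("rdcPopulationError",
           paste("unknown conformer id(s) in group", g))
    cf$group[idx] <- g
  }
  tbl@conformers <- cf
  tbl
}

#' Combine grouped populations and normalize over retained groups
#'
#' Per group, the combined population is the sum of the raw populations
#' of its retained members; normalized populations divide by the total
#' over all retained, grouped conformers so they sum to 1.
#'
#' @param tbl a \linkS4class{PopulationTable} with groups assigned and
#'   pruning applied.
#' @return the table with its \code{groups} slot populated.
#' @export
combineAndNormalize <- function(tbl) {
  cf <- conformerTable(tbl)
  use <- cf$retained & !is.na(cf$group)
  if (!any(use))
    .err("rdcPopulationError", "no retained conformers carry a group label")
  pComb <- tapply(cf$pRaw[use], cf$group[use], sum)
  g <- data.frame(group = names(pComb), pComb = as.numeric(pComb),
                  pNorm = as.numeric(pComb) / sum(pComb),
                  stringsAsFactors = FALSE)
  g <- g[order(g$group), , drop = FALSE]
  rownames(g) <- NULL
  tbl@groups <- g
  tbl
}
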