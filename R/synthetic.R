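## Synthetic structures, tensors and coupling tables with the
## statistical structure the analysis assumes: rigid molecules with C-H
## vectors in general position, Saupe tensors with GDO in the 1e-4 to
## 1e-3 range, homoscedastic Gaussian coupling noise, and two-conformer
## mixtures with a known mixing fraction. All generators are
## bit-reproducible given (spec, seed).

## Run fun() under a given seed without disturbing the caller's RNG
## state. Each generator draws from its own offset stream.
.withSeed <- function(seed, fun) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fun()
}

.SEED_OFFSET <- c(saupe = 101L, molecule = 211L, conformers = 307L,
                  noise = 401L)

#' Specification of a synthetic dataset
#'
#' Bundles the generator parameters: number of C-H vectors, target
#' generalized degree of order, Gaussian noise level (Hz), mixture
#' populations, RNG seed and geometry kind.
#'
#' @param nVectors number of C-H couplings (>= 5; default 15).
#' @param gdoTarget target GDO of the alignment tensor (default 5e-4,
#'   mid-range for weakly aligned small molecules).
#' @param noiseSigma Gaussian noise sigma in Hz (default 0.3, a typical
#'   coupling-extraction precision; >= 0).
#' @param populations mixture vector for ensembles (default 1).
#' @param seed integer seed fixing all randomness.
#' @param geometry one of \code{"random-rigid"}, \code{"template"},
#'   \code{"two-conformer-dihedral"}.
#' @param dihedralDeg rotation (degrees) distinguishing the two
#'   conformers of a two-conformer system (default 40).
#' @param minSeparationDeg minimum angular separation between generated
#'   C-H directions (default 5; guarantees rank-5 design matrices).
#' @return a validated list of class \code{"SimulationSpec"}.
#' @export
simulationSpec <- function(nVectors = 15, gdoTarget = 5e-4,
                           noiseSigma = 0.3, populations = 1,
                           seed = 1L,
                           geometry = c("random-rigid", "template",
                                        "two-conformer-dihedral"),
                           dihedralDeg = 40, minSeparationDeg = 5) {
  geometry <- match.arg(geometry)
  if (nVectors < 5) .err("rdcSimError", "nVectors must be >= 5")
  if (noiseSigma < 0) .err("rdcSimError", "noiseSigma must be >= 0")
  if (gdoTarget <= 0) .err("rdcSimError", "gdoTarget must be positive")
  populations <- as.numeric(populations)
  if (any(populations < 0) || abs(sum(populations) - 1) > 1e-9)
    .err("rdcSimError", "populations must form a valid simplex")
  structure(list(nVectors = as.integer(nVectors), gdoTarget = gdoTarget,
                 noiseSigma = noiseSigma, populations = populations,
                 seed = as.integer(seed), geometry = geometry,
                 dihedralDeg = dihedralDeg,
                 minSeparationDeg = minSeparationDeg),
            class = "SimulationSpec")
}

#' Random Saupe tensor with a prescribed GDO
#'
#' Draws the five independent elements from a standard normal and
#' rescales the matrix so its generalized degree of order equals
#' \code{gdoTarget} exactly. Deterministic per seed.
#'
#' @param gdoTarget target GDO (> 0).
#' @param seed integer seed.
#' @return a \linkS4class{SaupeTensor}.
#' @export
randomSaupe <- function(gdoTarget, seed = 1L) {
  if (gdoTarget <= 0) .err("rdcSimError", "gdoTarget must be positive")
  s <- .withSeed(seed + .SEED_OFFSET[["saupe"]], function() rnorm(5))
  S <- .vecToS(s)
  saupeTensor(S * (gdoTarget / sqrt(2 / 3 * sum(S^2))))
}

## n quasi-uniform unit vectors, pairwise separated by at least minSep
## degrees (also away from antipodal coincidence, which would produce
## degenerate design rows).
.sampleDirections <- function(n, minSep) {
  cosMin <- cos(minSep * pi / 180)
  dirs <- matrix(0, 0, 3)
  while (nrow(dirs) < n) {
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    if (nrow(dirs) == 0 || all(abs(dirs %*% v) < cosMin))
      dirs <- rbind(dirs, v)
  }
  dirs
}

.buildCHMolecule <- function(spec) {
  n <- spec$nVectors
  dirs <- .sampleDirections(n, spec$minSeparationDeg)
  i <- seq_len(n)
  ## non-collinear carbon skeleton: a loose helix, ~1.5 A rise
  cPos <- cbind(2.4 * cos(i * 0.9), 2.4 * sin(i * 0.9), 1.5 * i)
  hPos <- cPos + 1.09 * dirs
  list(dirs = dirs, cPos = cPos, hPos = hPos)
}

.assembleConformer <- function(id, cPos, hPos, eRel = NA_real_) {
  n <- nrow(cPos)
  conformer(id,
            label = c(paste0("C", seq_len(n)), paste0("H", seq_len(n))),
            element = c(rep("C", n), rep("H", n)),
            xyz = rbind(cPos, hPos), eRel = eRel)
}

#' Generate a rigid synthetic molecule with C-H vectors
#'
#' Creates \code{nVectors} C-H pairs at 1.09 Angstrom with bond
#' directions sampled quasi-uniformly on the sphere (no two within the
#' minimum separation angle, which guarantees rank-5 design matrices)
#' and a skeleton pair list with coupling class \code{"CH"}.
#'
#' @param spec a \code{\link{simulationSpec}}.
#' @return list with \code{conformer} (a \linkS4class{Conformer}) and
#'   \code{pairs} (data.frame atom1/atom2/type).
#' @export
makeRigidMolecule <- function(spec) {
  if (!spec$geometry %in% c("random-rigid", "template"))
    .err("rdcSimError", "geometry must be random-rigid or template")
  geom <- .withSeed(spec$seed + .SEED_OFFSET[["molecule"]],
                    function() .buildCHMolecule(spec))
  n <- spec$nVectors
  list(conformer = .assembleConformer("sim", geom$cPos, geom$hPos, eRel = 0),
       pairs = data.frame(atom1 = paste0("C", seq_len(n)),
                          atom2 = paste0("H", seq_len(n)),
                          type = "CH", stringsAsFactors = FALSE))
}

.rotationAboutZ <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

#' Generate a two-conformer system differing by a dihedral rotation
#'
#' Conformer B equals conformer A with the atoms of the second half of
#' the C-H pairs rotated rigidly by \code{dihedralDeg} about the z axis
#' (the common axis), emulating two ring/side-chain conformations of one
#' molecule. Labels are shared between the conformers.
#'
#' @param spec a \code{\link{simulationSpec}} with geometry
#'   \code{"two-conformer-dihedral"}.
#' @return list with \code{conformerA}, \code{conformerB},
#'   \code{pairs} and \code{movedPairs} (indices of the rotated subset).
#' @export
makeTwoConformerSystem <- function(spec) {
  if (spec$geometry != "two-conformer-dihedral")
    .err("rdcSimError", "geometry must be two-conformer-dihedral")
  geom <- .withSeed(spec$seed + .SEED_OFFSET[["conformers"]],
                    function() .buildCHMolecule(spec))
  n <- spec$nVectors
  moved <- seq.int(floor(n / 2) + 1L, n)
  R <- .rotationAboutZ(spec$dihedralDeg)
  cB <- geom$cPos; hB <- geom$hPos
  cB[moved, ] <- geom$cPos[moved, , drop = FALSE] %*% t(R)
  hB[moved, ] <- geom$hPos[moved, , drop = FALSE] %*% t(R)
  list(conformerA = .assembleConformer("confA", geom$cPos, geom$hPos, 0),
       conformerB = .assembleConformer("confB", cB, hB, 0.5),
       pairs = data.frame(atom1 = paste0("C", seq_len(n)),
                          atom2 = paste0("H", seq_len(n)),
                          type = "CH", stringsAsFactors = FALSE),
       movedPairs = moved)
}

#' Simulate an RDC dataset from known tensor and populations
#'
#' Forward model: after Eckart superposition onto the first conformer,
#' \eqn{D_i = \sum_k p_k\, scale_i\, \kappa_i\, e_{ik}^T S e_{ik}}, with
#' Gaussian noise of the spec's sigma added per record. sigD is set to
#' the noise sigma (or the 0.1 Hz floor for noiseless data). J is drawn
#' from N(145, 10^2) Hz and T = J + 2D is populated so that
#' \code{\link{extractRDC}} can be exercised on the emitted table.
#'
#' @param confs a \linkS4class{Conformer} or list of them.
#' @param S a \linkS4class{SaupeTensor} or symmetric traceless matrix.
#' @param pops populations (default: spec populations, padded to the
#'   number of conformers).
#' @param spec a \code{\link{simulationSpec}}.
#' @param pairs data.frame atom1/atom2/type; default pairs C_i with H_i
#'   by index from the first conformer's labels.
#' @return an \linkS4class{RDCDataset}.
#' @export
simulateRDCs <- function(confs, S, pops = NULL, spec, pairs = NULL) {
  if (!is.list(confs)) confs <- list(confs)
  if (is.null(pops)) {
    pops <- spec$populations
    if (length(pops) != length(confs))
      pops <- rep(1 / length(confs), length(confs))
  }
  pops <- as.numeric(pops)
  if (any(pops < 0) || abs(sum(pops) - 1) > 1e-9)
    .err("rdcSimError", "populations must form a valid simplex")
  if (is(S, "SaupeTensor")) S <- saupeMatrix(S)
  if (is.null(pairs)) {
    lab <- atoms(confs[[1]])$label
    cs <- grep("^C[0-9]+$", lab, value = TRUE)
    idx <- as.integer(sub("C", "", cs))
    pairs <- data.frame(atom1 = paste0("C", sort(idx)),
                        atom2 = paste0("H", sort(idx)),
                        type = "CH", stringsAsFactors = FALSE)
  }
  n <- nrow(pairs)
  d <- numeric(n)
  for (k in seq_along(confs)) {
    if (pops[k] == 0 && k > 1) next
    ck <- if (k == 1) confs[[1]] else eckartSuperpose(confs[[1]], confs[[k]])
    for (i in seq_len(n)) {
      ev <- effectiveVector(ck, pairs[i, , drop = FALSE])
      d[i] <- d[i] + pops[k] * ev$scale * ev$kappa *
        drop(t(ev$unitVec) %*% S %*% ev$unitVec)
    }
  }
  draws <- .withSeed(spec$seed + .SEED_OFFSET[["noise"]], function()
    list(noise = rnorm(n, 0, spec$noiseSigma), J = rnorm(n, 145, 10)))
  dNoisy <- d + draws$noise
  sigD <- if (spec$noiseSigma > 0) spec$noiseSigma else 0.1
  rdcDataset(atom1 = pairs$atom1, atom2 = pairs$atom2, type = pairs$type,
             J = draws$J, sigJ = 0.2, T = draws$J + 2 * dNoisy, sigT = 0.3,
             D = dNoisy, sigD = sigD,
             meta = list(generator = "simulateRDCs", seed = spec$seed,
                         populations = pops))
}
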