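test_that("superposing a conformer onto itself is the identity", {
  case <- makeRigidCase(n = 8, seed = 2)
  out <- eckartSuperpose(case$conf, case$conf)
  expect_equal(as.matrix(atoms(out)[, c("x", "y", "z")]),
               as.matrix(atoms(case$conf)[, c("x", "y", "z")]),
               tolerance = 1e-12)
  expect_lt(massWeightedRMSD(case$conf, out), 1e-12)
})

test_that("a known rigid transform is recovered to 1e-9 Angstrom", {
  case <- makeRigidCase(n = 8, seed = 3)
  set.seed(7)
  moved <- transformConformer(case$conf, randomRotation(), c(5, -3, 2))
  back <- eckartSuperpose(case$conf, moved)
  expect_lt(massWeightedRMSD(case$conf, back), 1e-9)
})

test_that("the Eckart rotation is minimal among random rotations", {
  specA <- simulationSpec(nVectors = 8, seed = 12,
                          geometry = "two-conformer-dihedral")
  sys <- makeTwoConformerSystem(specA)
  lab <- atoms(sys$conformerA)$label
  aligned <- eckartSuperpose(sys$conformerA, sys$conformerB, subset = lab)
  best <- massWeightedRMSD(sys$conformerA, aligned)
  set.seed(99)
  rmsds <- vapply(1:1000, function(i) {
    # any rigid alternative: random rotation, then optimal (centroid)
    # translation onto the reference
    trial <- transformConformer(sys$conformerB, randomRotation())
    trial <- centerOntoReference(sys$conformerA, trial)
    massWeightedRMSD(sys$conformerA, trial)
  }, numeric(1))
  expect_true(all(rmsds + 1e-12 >= best))
})

test_that("superposition preserves internal geometry", {
  specA <- simulationSpec(nVectors = 8, seed = 13,
                          geometry = "two-conformer-dihedral")
  sys <- makeTwoConformerSystem(specA)
  before <- dist(as.matrix(atoms(sys$conformerB)[, c("x", "y", "z")]))
  after <- dist(as.matrix(atoms(
    eckartSuperpose(sys$conformerA, sys$conformerB))[, c("x", "y", "z")]))
  expect_equal(as.numeric(after), as.numeric(before), tolerance = 1e-9)
})

test_that("superposition rejects label mismatch and collinear subsets", {
  case <- makeRigidCase(n = 8, seed = 2)
  other <- conformer("o", c("X1", "X2", "X3"), c("C", "C", "C"),
                     rbind(c(0, 0, 0), c(1, 0, 0), c(2, 1, 0)))
  expect_error(eckartSuperpose(case$conf, other), class = "rdcLabelError")
  lin <- conformer("l", c("C1", "C2", "C3"), c("C", "C", "C"),
                   rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  expect_error(eckartSuperpose(lin, lin), class = "rdcGeometryError")
})

test_that("a degenerate mixture reproduces the single-conformer fit exactly", {
  spec <- simulationSpec(nVectors = 10, noiseSigma = 0.3, seed = 21,
                         geometry = "two-conformer-dihedral")
  sys <- makeTwoConformerSystem(spec)
  S <- randomSaupe(5e-4, seed = 21)
  ds <- simulateRDCs(list(sys$conformerA, sys$conformerB), S,
                     pops = c(1, 0), spec = spec, pairs = sys$pairs)
  fitM <- fitMCST(list(sys$conformerA, sys$conformerB), c(1, 0), ds)
  fitS <- fitSCST(sys$conformerA, ds)
  expect_identical(records(fitM)$dCalc, records(fitS)$dCalc)  # bitwise
  expect_identical(fitQ(fitM), fitQ(fitS))
})

test_that("two identical conformers make the fit population independent", {
  case <- makeRigidCase(n = 10, noise = 0.3, seed = 22)
  confs <- list(case$conf, case$conf)
  f1 <- fitMCST(confs, c(0.2, 0.8), case$ds)
  f2 <- fitMCST(confs, c(0.9, 0.1), case$ds)
  expect_equal(records(f1)$dCalc, records(f2)$dCalc, tolerance = 1e-10)

  sc <- scanPopulations(confs, case$ds, step = 0.05)
  expect_lt(diff(range(qCurve(sc))), 1e-10)      # flat curve
  expect_equal(bestPopulation(sc), 0)            # tie -> smallest p1
})

test_that("population vectors are validated", {
  case <- makeRigidCase(n = 8, seed = 23)
  expect_error(fitMCST(list(case$conf, case$conf), c(0.7, 0.2), case$ds),
               class = "rdcPopulationError")
  expect_error(fitMCST(list(case$conf, case$conf), c(-0.1, 1.1), case$ds),
               class = "rdcPopulationError")
  expect_error(scanPopulations(list(case$conf), case$ds),
               class = "rdcPopulationError")
  expect_error(scanPopulations(list(case$conf, case$conf), case$ds,
                               step = 0.5),
               class = "rdcPopulationError")
})

test_that("a noiseless two-conformer mixture is recovered at its true p", {
  spec <- simulationSpec(nVectors = 15, noiseSigma = 0, seed = 31,
                         geometry = "two-conformer-dihedral")
  sys <- makeTwoConformerSystem(spec)
  S <- randomSaupe(5e-4, seed = 31)
  confs <- list(sys$conformerA, sys$conformerB)
  ds <- simulateRDCs(confs, S, pops = c(0.7, 0.3), spec = spec,
                     pairs = sys$pairs)
  fTrue <- fitMCST(confs, c(0.7, 0.3), ds)
  fWrong <- fitMCST(confs, c(0.5, 0.5), ds)
  expect_lt(fitQ(fTrue), 1e-8)
  expect_gt(fitQ(fWrong), 1e-4)

  sc <- scanPopulations(confs, ds, step = 0.01)
  expect_equal(bestPopulation(sc), 0.70)
  ep <- endpointFits(sc)
  expect_lte(fitQ(bestFit(sc)), min(fitQ(ep$p1), fitQ(ep$p0)))
})

test_that("the Q(p) curve is continuous across the grid", {
  spec <- simulationSpec(nVectors = 15, noiseSigma = 0.3, seed = 32,
                         geometry = "two-conformer-dihedral")
  sys <- makeTwoConformerSystem(spec)
  S <- randomSaupe(5e-4, seed = 32)
  confs <- list(sys$conformerA, sys$conformerB)
  ds <- simulateRDCs(confs, S, pops = c(0.6, 0.4), spec = spec,
                     pairs = sys$pairs)
  sc <- scanPopulations(confs, ds, step = 0.01)
  q <- qCurve(sc)
  slope <- max(abs(diff(q))) / 0.01
  expect_lt(max(abs(diff(q))), 10 * 0.01 * slope + 1e-12)
  # sanity rather than strictness: no isolated spikes
  expect_lt(max(abs(diff(q, lag = 1))), 0.2)
})
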