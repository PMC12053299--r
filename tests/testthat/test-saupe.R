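test_that("tensor descriptors: GDO, rhombicity, spectral invariance", {
  S <- diag(c(-0.5, -0.5, 1)) * 1e-3
  tn <- saupeTensor(S)
  expect_equal(gdo(tn), 1e-3, tolerance = 1e-12)   # sqrt(2/3 * 1.5e-6)
  expect_equal(rhombicity(tn), 0)
  expect_equal(axialComponent(tn), 5e-4, tolerance = 1e-12)

  z <- saupeTensor(matrix(0, 3, 3))
  expect_equal(gdo(z), 0)
  expect_equal(principalValues(z), c(0, 0, 0))

  set.seed(21)
  for (i in 1:20) {
    S <- randomTracelessMatrix()
    R <- randomRotation()
    t1 <- saupeTensor(S); t2 <- saupeTensor(R %*% S %*% t(R))
    expect_equal(principalValues(t2), principalValues(t1), tolerance = 1e-9)
    expect_equal(gdo(t2), gdo(t1), tolerance = 1e-12)
    expect_gte(rhombicity(t1), 0)
    expect_lte(rhombicity(t1), 2 / 3 + 1e-12)
    expect_equal(det(principalAxes(t1)), 1, tolerance = 1e-9)
  }
  expect_error(saupeTensor(matrix(1, 3, 3) + diag(1, 3)),
               class = "rdcTensorError")
})

test_that("quality factor matches its definition and invariances", {
  expect_equal(qFactor(c(10, -5, 8), c(10, -5, 8)), 0)
  # frozen oracle sqrt(3/189)
  expect_equal(qFactor(c(10, -5, 8), c(9, -4, 7)), 0.1259882,
               tolerance = 1e-6)
  # homogeneity
  expect_equal(qFactor(3.7 * c(10, -5, 8), 3.7 * c(9, -4, 7)),
               qFactor(c(10, -5, 8), c(9, -4, 7)))
  expect_error(qFactor(c(0, 0), c(1, 1)), class = "rdcQError")
  expect_error(qFactor(1:3, 1:2), class = "rdcQError")
})

test_that("design matrix reproduces the axis-aligned closed form", {
  conf <- conformer("c", c("C1", "H1", "C2", "H2", "C3", "H3", "C4", "H4",
                           "C5", "H5"),
                    rep(c("C", "H"), 5),
                    rbind(c(0, 0, 0), c(0, 0, 1.09),
                          c(3, 0, 0), c(3 + 1.09, 0, 0),
                          c(6, 0, 0), c(6, 1.09, 0),
                          c(9, 0, 0), c(9, 0.7707, 0.7707),
                          c(12, 0, 0), c(12.7707, 0, 0.7707)))
  ds <- rdcDataset(paste0("C", 1:5), paste0("H", 1:5), D = c(5, 1, 1, 2, 2),
                   sigD = 0.2)
  sys <- buildDesignMatrix(conf, ds)
  # bond along z with S = diag(-1/2,-1/2,1)*s0 predicts D = kappa*s0
  s0 <- 1e-4
  sVec <- c(-s0 / 2, -s0 / 2, 0, 0, 0)
  pred <- drop(sys$A %*% sVec)
  expect_equal(pred[1], dipolarPrefactor("CH", 1.09) * s0, tolerance = 1e-9)
  expect_equal(sys$w, rep(1 / 0.2, 5))
})

test_that("collinear record sets give rank-1 design matrices, not errors", {
  n <- 6
  cPos <- cbind(3 * seq_len(n), 0, 0)
  hPos <- cPos + matrix(rep(c(0, 0, 1.09), n), n, 3, byrow = TRUE)
  conf <- conformer("c", c(paste0("C", 1:n), paste0("H", 1:n)),
                    c(rep("C", n), rep("H", n)), rbind(cPos, hPos))
  ds <- rdcDataset(paste0("C", 1:n), paste0("H", 1:n), D = rnorm(n),
                   sigD = 0.2)
  sys <- buildDesignMatrix(conf, ds)
  expect_equal(qr(sys$A)$rank, 1)
  fit <- suppressWarnings(fitSCST(conf, ds))
  expect_true(fit@rankDeficient)
  expect_identical(fit@condition, Inf)
})

test_that("noiseless synthetic RDCs are recovered exactly", {
  case <- makeRigidCase(n = 10, gdoTarget = 5e-4, noise = 0, seed = 1)
  fit <- fitSCST(case$conf, case$ds)
  expect_lt(max(abs(saupeMatrix(fitTensor(fit)) - saupeMatrix(case$S))),
            1e-10 * sqrt(sum(saupeMatrix(case$S)^2)))
  expect_lt(fitQ(fit), 1e-10)
  # design-matrix round trip against the simulator
  sys <- buildDesignMatrix(case$conf, case$ds)
  S <- saupeMatrix(case$S)
  sTrue <- c(S[1, 1], S[2, 2], S[1, 2], S[1, 3], S[2, 3])
  expect_equal(drop(sys$A %*% sTrue), sys$d, tolerance = 1e-9)
})

test_that("SVD solution equals brute-force weighted normal equations", {
  set.seed(33)
  for (i in 1:20) {
    n <- sample(5:12, 1)
    A <- matrix(rnorm(5 * n), n, 5)
    d <- rnorm(n)
    w <- runif(n, 0.5, 5)
    sol <- rdctensor:::.svdSolve(A, d, w)
    W2 <- diag(w^2)
    oracle <- solve(t(A) %*% W2 %*% A, t(A) %*% W2 %*% d)
    expect_equal(sol$s, drop(oracle), tolerance = 1e-9)
  }
})

test_that("fits are rotation equivariant with identical Q", {
  case <- makeRigidCase(n = 12, noise = 0.3, seed = 4)
  fit0 <- fitSCST(case$conf, case$ds)
  set.seed(5)
  R <- randomRotation()
  fitR <- fitSCST(transformConformer(case$conf, R, c(1, -2, 3)), case$ds)
  expect_equal(saupeMatrix(fitTensor(fitR)),
               R %*% saupeMatrix(fitTensor(fit0)) %*% t(R),
               tolerance = 1e-9)
  expect_equal(fitQ(fitR), fitQ(fit0), tolerance = 1e-9)
})

test_that("Q and tensor direction are invariant under data rescaling", {
  case <- makeRigidCase(n = 10, noise = 0.3, seed = 6)
  r <- records(case$ds)
  scaled <- rdcDataset(r$atom1, r$atom2, r$type, D = 10 * r$D,
                       sigD = 10 * r$sigD)
  f1 <- fitSCST(case$conf, case$ds)
  f2 <- fitSCST(case$conf, scaled)
  expect_equal(fitQ(f2), fitQ(f1), tolerance = 1e-12)
  S1 <- saupeMatrix(fitTensor(f1)); S2 <- saupeMatrix(fitTensor(f2))
  expect_equal(S2 / sqrt(sum(S2^2)), S1 / sqrt(sum(S1^2)), tolerance = 1e-9)
})

test_that("weighted fit with equal sigmas equals the unweighted fit", {
  case <- makeRigidCase(n = 10, noise = 0.5, seed = 8)
  fw <- fitSCST(case$conf, case$ds, weighted = TRUE)
  fu <- fitSCST(case$conf, case$ds, weighted = FALSE)
  expect_equal(saupeMatrix(fitTensor(fw)), saupeMatrix(fitTensor(fu)),
               tolerance = 1e-12)
})

test_that("median Q grows with the noise level", {
  sigmas <- c(0, 0.3, 1)
  medQ <- vapply(sigmas, function(sg) {
    qs <- vapply(1:40, function(i) {
      case <- makeRigidCase(n = 10, noise = sg, seed = 1000 + i)
      fitQ(fitSCST(case$conf, case$ds))
    }, numeric(1))
    median(qs)
  }, numeric(1))
  expect_true(all(diff(medQ) >= 0))
})

test_that("error floor applies to records lacking an error estimate", {
  case <- makeRigidCase(n = 8, noise = 0.3, seed = 10)
  r <- records(case$ds)
  noSig <- rdcDataset(r$atom1, r$atom2, r$type, D = r$D)
  sys <- buildDesignMatrix(case$conf, noSig, sigmaFloor = 0.1)
  expect_equal(sys$w, rep(10, 8))
  expect_true(sys$flooredAny)
  expect_error(buildDesignMatrix(case$conf,
                                 rdcDataset(r$atom1[1:4], r$atom2[1:4],
                                            D = r$D[1:4], sigD = 0.2)),
               class = "rdcFitError")
})
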