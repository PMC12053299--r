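# Fixtures built in code: small geometries and tensors shared by tests.

# Water-like 3-atom geometry for round-trip checks
makeWater <- function() {
  conformer("water",
            label = c("O1", "H1", "H2"),
            element = c("O", "H", "H"),
            xyz = rbind(c(0, 0, 0.117351),
                        c(0, 0.757, -0.469402),
                        c(0, -0.757, -0.469402)))
}

# Ideal tetrahedral methyl group: methyl carbon at the origin, the
# axis-defining neighbour carbon on +z, three H at exactly
# cos(H-C-axis) = -1/3.
makeIdealMethyl <- function(rCH = 1.09) {
  hz <- -1 / 3
  hr <- sqrt(8) / 3
  az <- c(0, 2 * pi / 3, 4 * pi / 3)
  h <- rCH * cbind(hr * cos(az), hr * sin(az), rep(hz, 3))
  conformer("methyl",
            label = c("C1", "C2", "H1", "H2", "H3"),
            element = c("C", "C", "H", "H", "H"),
            xyz = rbind(c(0, 0, 0), c(0, 0, 1.52), h))
}

# Random symmetric traceless 3x3 matrix (plain matrix, not SaupeTensor)
randomTracelessMatrix <- function(scale = 1e-4) {
  s <- rnorm(5)
  matrix(c(s[1], s[3], s[4],
           s[3], s[2], s[5],
           s[4], s[5], -s[1] - s[2]), 3, 3) * scale
}

# Random proper rotation via QR
randomRotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Apply a rigid transform to a conformer's coordinates
transformConformer <- function(conf, R = diag(3), t = c(0, 0, 0)) {
  a <- atoms(conf)
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, t, `+`)
  conformer(conf@id, a$label, a$element, xyz, mass = a$mass,
            eRel = relEnergy(conf))
}

# Translate conf so its mass-weighted centroid coincides with ref's
centerOntoReference <- function(ref, conf) {
  ra <- atoms(ref); ca <- atoms(conf)
  cRef <- colSums(as.matrix(ra[, c("x", "y", "z")]) * ra$mass) / sum(ra$mass)
  cMov <- colSums(as.matrix(ca[, c("x", "y", "z")]) * ca$mass) / sum(ca$mass)
  transformConformer(conf, diag(3), cRef - cMov)
}

# Simulated rigid system: conformer, dataset and the true tensor
makeRigidCase <- function(n = 10, gdoTarget = 5e-4, noise = 0, seed = 42) {
  spec <- simulationSpec(nVectors = n, gdoTarget = gdoTarget,
                         noiseSigma = noise, seed = seed)
  sim <- makeRigidMolecule(spec)
  S <- randomSaupe(gdoTarget, seed = seed)
  ds <- simulateRDCs(sim$conformer, S, pops = 1, spec = spec,
                     pairs = sim$pairs)
  list(conf = sim$conformer, ds = ds, S = S, spec = spec)
}

# Galantamine-style conformer population table (in-text values)
makeEnsembleTable <- function() {
  populationTable(conf = c("01", "02", "03", "04", "05", "06"),
                  eRel = c(0.000, 0.108, 1.496, 1.935, 2.258, 2.449),
                  pRaw = c(0.4881, 0.4064, 0.0391, 0.0187, 0.0048, 0.0052))
}
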