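## Physical constants (SI) and atomic masses used throughout.
## Gyromagnetic ratios: CODATA values, rad s^-1 T^-1.

.MU0 <- 4 * pi * 1e-7            # vacuum permeability, T m A^-1
.PLANCK_H <- 6.62607015e-34      # Planck constant, J s
.GAMMA <- c(
  H = 2.6752218744e8,
  C = 6.728284e7,
  N = -2.7116e7,
  P = 1.08394e8,
  F = 2.51815e8
)

## Boltzmann constant in kcal mol^-1 K^-1 (gas constant / 1000 cal)
.KB_KCAL <- 0.0019872041

## Standard atomic weights (u), sufficient for organic analytes.
.ATOMIC_MASS <- c(
  H = 1.008, D = 2.014, He = 4.0026,
  B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Si = 28.085, P = 30.974, S = 32.06,
  Cl = 35.45, K = 39.098, Ca = 40.078, Br = 79.904, I = 126.904
)

atomicMass <- function(element) {
  m <- .ATOMIC_MASS[element]
  if (anyNA(m)) {
    stop("unknown element symbol(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "),
         call. = FALSE)
  }
  unname(m)
}

gyromagneticRatio <- function(nucleus) {
  g <- .GAMMA[nucleus]
  if (anyNA(g)) {
    stop("no tabulated gyromagnetic ratio for nucleus: ",
         paste(unique(nucleus[is.na(g)]), collapse = ", "),
         call. = FALSE)
  }
  unname(g)
}
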