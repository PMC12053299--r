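## Comparison of alignment tensors through the generalized 5D angle,
## used to quantify enantiodifferentiation between mirror-image media.

#' Generalized 5D angle between two alignment tensors
#'
#' \eqn{\beta = \arccos\left(\langle S_1, S_2\rangle_F /
#' (\|S_1\|_F \|S_2\|_F)\right)} in degrees, where the Frobenius inner
#' product over the full 3x3 matrices equals the scalar product of the
#' five-dimensional irreducible representations. 0 degrees means the two
#' tensors orient the molecule identically (no observable
#' enantiodifferentiation); 90 degrees is maximal enantiodifferentiation.
#'
#' @param S1,S2 symmetric traceless 3x3 matrices or
#'   \linkS4class{SaupeTensor} objects.
#' @return angle in degrees, within [0, 180].
#' @export
betaAngle <- function(S1, S2) {
  if (is(S1, "SaupeTensor")) S1 <- saupeMatrix(S1)
  if (is(S2, "SaupeTensor")) S2 <- saupeMatrix(S2)
  n1 <- sqrt(sum(S1^2)); n2 <- sqrt(sum(S2^2))
  if (n1 == 0 || n2 == 0)
    .err("rdcTensorError", "beta angle is undefined for a zero tensor")
  ## numerically stable arccos of the normalized Frobenius product:
  ## 2 atan2(|u - v|, |u + v|) is exact at 0 and 180 degrees where the
  ## plain acos loses half its digits
  u <- S1 / n1; v <- S2 / n2
  2 * atan2(sqrt(sum((u - v)^2)), sqrt(sum((u + v)^2))) * 180 / pi
}

#' Compare the alignment tensors of two fits
#'
#' Computes the 5D angle between the tensors fitted to the same analyte
#' in two media (e.g. the two enantiomers of a chiral alignment medium)
#' together with the ratio of their generalized degrees of order. By
#' default no mirror operation is applied: the two fitted tensors are
#' compared directly. With \code{mirror = TRUE} the second tensor is
#' transformed as if its structure had been reflected through the xz
#' plane (y negated) before fitting, i.e. the signs of S_xy and S_yz are
#' flipped.
#'
#' @param fit1,fit2 \linkS4class{RDCFit} objects (or
#'   \linkS4class{SaupeTensor}s) for the same structure in the same
#'   coordinate frame.
#' @param mirror apply the reflection convention to the second tensor
#'   (default FALSE).
#' @return a \linkS4class{TensorComparison}.
#' @export
compareTensors <- function(fit1, fit2, mirror = FALSE) {
  t1 <- if (is(fit1, "RDCFit")) fitTensor(fit1) else fit1
  t2 <- if (is(fit2, "RDCFit")) fitTensor(fit2) else fit2
  S2 <- saupeMatrix(t2)
  note <- "no mirror operation applied"
  if (mirror) {
    M <- diag(c(1, -1, 1))
    S2 <- M %*% S2 %*% M
    note <- "tensor 2 mirrored through the xz plane (y negated)"
  }
  new("TensorComparison",
      betaDeg = betaAngle(saupeMatrix(t1), S2),
      gdoRatio = gdo(t1) / gdo(t2),
      frameNote = note)
}
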