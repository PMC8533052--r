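# Semantics-details aggregation (SDA): a reconstructed skip connection.
# Upsampled deep semantics (F) are squeezed by a 3x3 conv to the
# encoder's channel count and multiplicatively gate the encoder detail
# map (E); the gated detail is added to the decoder stream (D):
#   S = Conv(up2(F)) * E + D
# No normalization or activation inside the module.

#' Initialize SDA parameters
#'
#' @param cF channels of the deep source feature map F.
#' @param cE channels of the encoder/decoder maps E and D.
#' @return list with the 3x3 squeeze convolution (`conv`).
#' @export
sdaInit <- function(cF, cE) list(conv = convInit(3, cF, cE))

#' SDA forward pass
#'
#' @param F deep-stage feature map (h/2, w/2, cF, n): Decoder 3 output
#'   for the first instance, SDA 1 output for the second.
#' @param E encoder detail map (h, w, cE, n).
#' @param D decoder semantic map, same shape as `E`.
#' @param params parameter list from [sdaInit()].
#' @return feature map with the shape of `E`.
#' @export
sdaForward <- function(F, E, D, params) {
  sdaFwd(as4d(F), as4d(E), as4d(D), params)$y
}

sdaFwd <- function(F, E, D, p) {
  dE <- dim(E)
  dF <- dim(F)
  if (!identical(dim(D), dE))
    stop("SDA: decoder map D dims (", paste(dim(D), collapse = "x"),
         ") must equal encoder map E dims (", paste(dE, collapse = "x"), ")")
  if (2L * dF[1] != dE[1] || 2L * dF[2] != dE[2])
    stop("SDA: F spatial dims must be half of E's (got ",
         paste(dF[1:2], collapse = "x"), " vs ",
         paste(dE[1:2], collapse = "x"), ")")
  up <- up2Fwd(F)
  gate <- convFwd(up, p$conv, 1L)
  if (!identical(dim(gate), dE))
    stop("SDA: squeeze conv output channels (", dim(gate)[3],
         ") must equal E channels (", dE[3], ")")
  list(y = gate * E + D, F = F, up = up, gate = gate, E = E)
}

sdaBwd <- function(dy, cache, p) {
  dgate <- dy * cache$E
  dE <- dy * cache$gate
  g <- convBwd(cache$up, p$conv, dgate, 1L)
  dF <- up2Bwd(g$dx)
  list(dF = dF, dE = dE, dD = dy,
       grads = list(conv = list(W = g$dW, b = g$db)))
}

#' Wire the two SDA instances of MF-Net
#'
#' The first SDA gates Encoder 2 detail with upsampled Decoder 3 output
#' and adds Decoder 2; its output is in turn the deep source for the
#' second SDA, which gates Encoder 1 detail and adds Decoder 1. No skip
#' path exists from Encoder 3 or Encoder 4.
#'
#' @param decoder3Out Decoder 3 output (deep source F1).
#' @param E2,D2 Encoder 2 / Decoder 2 feature maps.
#' @param E1,D1 Encoder 1 / Decoder 1 feature maps.
#' @param params1,params2 parameter lists from [sdaInit()].
#' @return list with elements `S1` and `S2`.
#' @export
wireSdaChain <- function(decoder3Out, E2, D2, E1, D1, params1, params2) {
  S1 <- sdaForward(decoder3Out, E2, D2, params1)
  S2 <- sdaForward(S1, E1, D1, params2)
  list(S1 = S1, S2 = S2)
}
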