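# 3D Hilbert curve via Skilling's transpose algorithm (AIP Conf. Proc. 707,
# 381, 2004). Index bits are interleaved across the three axes ("transpose"
# form), Gray-decoded, then the excess rotations are undone. Consecutive
# indices map to lattice sites one unit apart, and every site of the
# 2^order cube is visited exactly once.

hilbert_transpose_to_axes <- function(X, bits) {
  N <- bitwShiftL(2L, bits - 1L)
  # Gray decode
  t <- bitwShiftR(X[3], 1L)
  for (i in 3:2) X[i] <- bitwXor(X[i], X[i - 1])
  X[1] <- bitwXor(X[1], t)
  # undo excess work
  Q <- 2L
  while (Q != N) {
    P <- Q - 1L
    for (i in 3:1) {
      if (bitwAnd(X[i], Q) != 0L) {
        X[1] <- bitwXor(X[1], P)
      } else {
        tt <- bitwAnd(bitwXor(X[1], X[i]), P)
        X[1] <- bitwXor(X[1], tt)
        X[i] <- bitwXor(X[i], tt)
      }
    }
    Q <- bitwShiftL(Q, 1L)
  }
  X
}

hilbert_curve_3d <- function(order) {
  bits <- order
  npts <- 8L^order
  coords <- matrix(0L, npts, 3L)
  for (d in 0:(npts - 1L)) {
    X <- integer(3)
    for (i in 0:(3L * bits - 1L)) {          # bit i, MSB first
      b <- bitwAnd(bitwShiftR(d, 3L * bits - 1L - i), 1L)
      ax <- i %% 3L + 1L
      X[ax] <- bitwOr(bitwShiftL(X[ax], 1L), b)
    }
    coords[d + 1L, ] <- hilbert_transpose_to_axes(X, bits)
  }
  coords
}
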