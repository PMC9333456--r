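## Independent oracles and small utilities shared across the test files.

## Quaternion (Horn) method for the optimal-superposition RMSD; independent
## of the SVD route used by the package.
quaternionRmsd <- function(a, b) {
  A <- sweep(a, 2, colMeans(a)); B <- sweep(b, 2, colMeans(b))
  M <- crossprod(B, A)
  S <- matrix(0, 4, 4)
  S[1, 1] <- M[1, 1] + M[2, 2] + M[3, 3]
  S[1, 2] <- S[2, 1] <- M[2, 3] - M[3, 2]
  S[1, 3] <- S[3, 1] <- M[3, 1] - M[1, 3]
  S[1, 4] <- S[4, 1] <- M[1, 2] - M[2, 1]
  S[2, 2] <- M[1, 1] - M[2, 2] - M[3, 3]
  S[2, 3] <- S[3, 2] <- M[1, 2] + M[2, 1]
  S[2, 4] <- S[4, 2] <- M[1, 3] + M[3, 1]
  S[3, 3] <- -M[1, 1] + M[2, 2] - M[3, 3]
  S[3, 4] <- S[4, 3] <- M[2, 3] + M[3, 2]
  S[4, 4] <- -M[1, 1] - M[2, 2] + M[3, 3]
  lam <- max(eigen(S, symmetric = TRUE)$values)
  sqrt(max(0, (sum(A^2) + sum(B^2) - 2 * lam) / nrow(a)))
}

randomRotation <- function() {
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

rotateStructure <- function(s, R = randomRotation(), shift = c(5, -3, 8)) {
  m <- as.matrix(s@atoms[, c("x", "y", "z")]) %*% t(R)
  s@atoms$x <- m[, 1] + shift[1]
  s@atoms$y <- m[, 2] + shift[2]
  s@atoms$z <- m[, 3] + shift[3]
  s
}
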