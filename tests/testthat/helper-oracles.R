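# Independent oracle implementations, deliberately coded differently from
# the package internals so they can serve as cross-checks.

# torsion via the direct atan2 cross-product formula
oracleDihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cx <- function(a, b) c(a[2]*b[3]-a[3]*b[2], a[3]*b[1]-a[1]*b[3],
                         a[1]*b[2]-a[2]*b[1])
  n1 <- cx(b1, b2); n2 <- cx(b2, b3)
  y <- sum(cx(n1, n2) * b2) / sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  a <- atan2(y, x) * 180 / pi
  if (a <= -180) a + 360 else a
}

# second internal-to-Cartesian implementation: rotation-matrix chain frames
# (independent of the package's NeRF vector construction)
oracleChainCA <- function(phi, psi, omega, nca = 0.1458, cac = 0.1525,
                          cn = 0.1329, angNCAC = 111.0, angCACN = 116.2,
                          angCNCA = 121.7) {
  rad <- function(d) d * pi / 180
  place <- function(a, b, c_, r, ang, tor) {
    # rotation about the b->c axis by the torsion, starting from the
    # in-plane direction at the bond angle
    bc <- (c_ - b); bc <- bc / sqrt(sum(bc^2))
    ba <- (a - b)
    u <- ba - sum(ba * bc) * bc
    u <- u / sqrt(sum(u^2))
    v <- c(bc[2]*u[3]-bc[3]*u[2], bc[3]*u[1]-bc[1]*u[3], bc[1]*u[2]-bc[2]*u[1])
    th <- rad(ang); ch <- rad(tor)
    d <- -cos(th) * bc + sin(th) * (cos(ch) * u + sin(ch) * v)
    c_ + r * d
  }
  n <- length(phi)
  N <- c(0, 0, 0); CA <- c(nca, 0, 0)
  C <- place(c(0, 1, 0), N, CA, cac, angNCAC, phi[1])
  cas <- matrix(NA_real_, n, 3); cas[1, ] <- CA
  for (i in seq_len(n - 1)) {
    N2 <- place(N, CA, C, cn, angCACN, psi[i])
    CA2 <- place(CA, C, N2, nca, angCNCA, omega[i + 1])
    C2 <- place(C, N2, CA2, cac, angNCAC, phi[i + 1])
    N <- N2; CA <- CA2; C <- C2
    cas[i + 1, ] <- CA
  }
  cas
}

# brute-force double-loop radius of gyration
oracleRg <- function(x, m = rep(1, nrow(x))) {
  com <- c(sum(x[, 1] * m), sum(x[, 2] * m), sum(x[, 3] * m)) / sum(m)
  acc <- 0
  for (i in seq_len(nrow(x)))
    acc <- acc + m[i] * sum((x[i, ] - com)^2)
  sqrt(acc / sum(m))
}

# brute-force Kirkwood inverse-distance sum
oracleKirkwoodRh <- function(x) {
  N <- nrow(x)
  acc <- 0
  for (i in seq_len(N)) for (j in seq_len(N)) if (i != j)
    acc <- acc + 1 / sqrt(sum((x[i, ] - x[j, ])^2))
  1 / (acc / N^2)
}

# random rigid-body transform
randomRigidTransform <- function(x) {
  th <- stats::runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  Ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0),
              c(-sin(th[2]), 0, cos(th[2])))
  Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
              c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
  t(Rz %*% Ry %*% Rx %*% t(x)) + matrix(stats::runif(3, -5, 5),
                                        nrow(x), 3, byrow = TRUE)
}

# grid + bisection minimizer of the 1-D BME dual for a single restraint
oracleBMELambda <- function(w0, f, o, sigma, theta) {
  gamma <- function(l) {
    z <- sum(w0 * exp(-l * f))
    log(z) + l * o + (theta / 2) * l^2 * sigma^2
  }
  grid <- seq(-200, 200, length.out = 4001)
  gv <- vapply(grid, gamma, numeric(1))
  i <- which.min(gv)
  lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
  for (k in 1:200) {
    m1 <- lo + (hi - lo) / 3; m2 <- hi - (hi - lo) / 3
    if (gamma(m1) < gamma(m2)) hi <- m2 else lo <- m1
  }
  (lo + hi) / 2
}

# shared small ensemble for expensive fixtures (built once per test run)
.cachedEnsembles <- new.env()
cachedEnsemble <- function(key, config) {
  if (is.null(.cachedEnsembles[[key]]))
    .cachedEnsembles[[key]] <- sampleEnsemble(config)
  .cachedEnsembles[[key]]
}
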